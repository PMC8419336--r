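# Seed handling: every generator is a pure function of (seed, parameters).
# A single user-facing seed fans out to per-component child seeds through a
# fixed counter scheme, so adding replicates or timepoints never shifts the
# draws of earlier components. Child seeds stay below 2^31 - 1.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

child_seed <- function(seed, counter) {
  (as.double(seed) * 1000003 + counter * 7919) %% 2147483629
}

#' Draw a uniformly random clonal hierarchy
#'
#' Samples uniformly over the fixed-root labeled trees on `n` nodes by
#' drawing a uniform Pruefer sequence (each of the n^(n-2) sequences maps to
#' exactly one tree). In `founder` mode the nodes are mutations `m1..mn`
#' rooted at `m1`; in `wildtype` mode the root is the reserved reference
#' allele `WT` followed by `m1..m(n-1)`.
#'
#' @param n clone count (wildtype mode: including the wild-type clone).
#' @param seed optional integer for reproducibility.
#' @param mode `"founder"` or `"wildtype"`.
#' @param wt_id reserved wild-type label.
#' @return a [clonal_tree()].
#' @export
random_tree <- function(n, seed = NULL, mode = c("founder", "wildtype"),
                        wt_id = "WT") {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  labels <- if (mode == "founder") paste0("m", seq_len(n))
            else c(wt_id, paste0("m", seq_len(n - 1L)))
  if (n == 1L)
    return(clonal_tree(stats::setNames(NA_character_, labels)))
  with_seed(seed, {
    s <- if (n == 2L) integer(0) else sample.int(n, n - 2L, replace = TRUE)
    root_edges(prufer_to_tree(s, n), 1L, labels)
  })
}

#' Draw random clone frequencies on the simplex
#'
#' Symmetric Dirichlet(alpha) draw; `alpha = 1` is uniform on the simplex,
#' the least-informative model of "a random distribution among the
#' different clones". Optionally rejection-samples until every clone
#' frequency reaches `min_clone_freq`.
#'
#' @param n clone count.
#' @param seed optional integer.
#' @param alpha Dirichlet concentration, > 0.
#' @param min_clone_freq optional lower bound per clone (fraction).
#' @return numeric vector summing to 1.
#' @export
random_frequencies <- function(n, seed = NULL, alpha = 1,
                               min_clone_freq = NULL) {
  n <- as.integer(n)
  if (n < 1L || alpha <= 0) stop("'n' must be >= 1 and 'alpha' > 0")
  if (!is.null(min_clone_freq) && n * min_clone_freq > 1)
    stop("min_clone_freq infeasible: n * min_clone_freq > 1")
  with_seed(seed, {
    repeat {
      g <- stats::rgamma(n, shape = alpha)
      f <- g / sum(g)
      if (is.null(min_clone_freq) || all(f >= min_clone_freq)) return(f)
    }
  })
}

#' Simulate a synthetic leukemia patient
#'
#' End-to-end generator emulating the study design the reconstruction is
#' tested against: a small number of clones related by a rooted mutation
#' tree, heterozygous mutations, clone frequencies on the simplex, and
#' samples at diagnosis and relapse. Draws the true hierarchy once, clone
#' frequencies independently per timepoint, then (with a finite `n_cells`)
#' a multinomial single-cell clone table per timepoint; bulk VAFs are
#' computed from the single-cell table and optionally perturbed with
#' Gaussian measurement noise.
#'
#' @param n clone count (2-7 matches the observed patient range).
#' @param timepoints character vector of timepoint labels.
#' @param n_cells sequenced cells per timepoint; `NULL` for the exact-
#'   frequency (infinite-sample) dataset.
#' @param vaf_noise_sd Gaussian VAF noise in percentage points (0 = exact).
#' @param seed optional integer; the patient is a pure function of it.
#' @param alpha Dirichlet concentration for the clone frequencies.
#' @param min_clone_freq optional lower bound per clone frequency.
#' @param mode `"founder"` or `"wildtype"` tree space.
#' @return object of class `synthetic_patient` with the true tree, per-
#'   timepoint frequencies, single-cell datasets, bulk samples and the
#'   generation parameters.
#' @examples
#' p <- simulate_patient(4, seed = 7)
#' length(reconstruct(p$bulk_by_timepoint)$exact_fits) >= 1
#' @export
simulate_patient <- function(n, timepoints = c("diagnosis", "relapse"),
                             n_cells = 500, vaf_noise_sd = 0, seed = NULL,
                             alpha = 1, min_clone_freq = NULL,
                             mode = "founder") {
  if (vaf_noise_sd < 0) stop("'vaf_noise_sd' must be non-negative")
  truth <- random_tree(n, seed = if (is.null(seed)) NULL
                                 else child_seed(seed, 0L), mode = mode)
  freqs <- list(); sc <- list(); bulk <- list()
  for (i in seq_along(timepoints)) {
    tp <- timepoints[i]
    f <- random_frequencies(n, seed = if (is.null(seed)) NULL
                                      else child_seed(seed, i),
                            alpha = alpha, min_clone_freq = min_clone_freq)
    f <- stats::setNames(f, depth_order(truth))
    freqs[[tp]] <- f
    if (is.null(n_cells)) {
      sc[[tp]] <- sc_dataset_from_tree(truth, frequencies = f,
                                       timepoint = tp)
    } else {
      counts <- with_seed(if (is.null(seed)) NULL
                          else child_seed(seed, 100L + i),
                          as.integer(stats::rmultinom(1, n_cells, f)))
      sc[[tp]] <- sc_dataset_from_tree(truth,
                                       counts = stats::setNames(counts,
                                                                names(f)),
                                       timepoint = tp)
    }
    b <- bulk_vaf_from_sc(sc[[tp]])
    if (vaf_noise_sd > 0)
      b <- perturb_vafs(b, sd = vaf_noise_sd, n_reps = 1,
                        seed = if (is.null(seed)) NULL
                               else child_seed(seed, 200L + i))[[1L]]
    bulk[[tp]] <- b
  }
  structure(
    list(truth = truth,
         frequencies_by_timepoint = freqs,
         sc_by_timepoint = sc,
         bulk_by_timepoint = bulk,
         seed = seed,
         provenance = list(n = n, timepoints = timepoints,
                           n_cells = n_cells, vaf_noise_sd = vaf_noise_sd,
                           alpha = alpha, min_clone_freq = min_clone_freq,
                           mode = mode)),
    class = "synthetic_patient"
  )
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("Synthetic patient:", x$provenance$n, "clones,",
      length(x$provenance$timepoints), "timepoint(s)",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  cat("  truth: ", write_newick(x$truth), "\n", sep = "")
  invisible(x)
}
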