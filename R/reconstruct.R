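#' Normalize a VAF sample to the founder convention
#'
#' Rescales all frequencies of one timepoint so that the most abundant
#' mutation sits at 100 percent. Under the founder-mode assumptions
#' (single founding mutation, heterozygous variants, purely leukemic sample)
#' this puts the founder allele at 100 and makes the clone frequencies sum
#' to 100.
#'
#' @param sample a [vaf_sample()].
#' @return the rescaled [vaf_sample()] (idempotent on normalized input).
#' @export
normalize_vafs <- function(sample) {
  stopifnot(inherits(sample, "vaf_sample"))
  m <- max(sample$vaf)
  if (m <= 0) stop("cannot normalize an all-zero sample")
  vaf_sample(sample$allele_ids, sample$vaf * (100 / m),
             timepoint = sample$timepoint,
             weights = unname(sample$weights))
}

as_sample_list <- function(samples) {
  if (inherits(samples, "vaf_sample")) samples <- list(samples)
  if (!length(samples) || !all(vapply(samples, inherits, logical(1),
                                      "vaf_sample")))
    stop("'samples' must be a vaf_sample or a non-empty list of them")
  tps <- vapply(samples, function(s) s$timepoint, character(1))
  if (anyDuplicated(tps)) stop("duplicate timepoint labels: ",
                               paste(tps[duplicated(tps)], collapse = ", "))
  stats::setNames(samples, tps)
}

#' Add a wild-type root allele to every timepoint
#'
#' For samples with several founding clones (or an unsequenced common
#' founder), a healthy reference allele that is present in all cells is
#' appended at frequency 100 so that reconstruction can root every tree at
#' the healthy phenotype.
#'
#' @param samples a [vaf_sample()] or list of them (one per timepoint).
#' @param wt_id reserved reference-allele identifier.
#' @return list of samples, each with the reference allele at 100.
#' @export
add_wildtype_root <- function(samples, wt_id = "WT") {
  samples <- as_sample_list(samples)
  lapply(samples, function(s) {
    if (wt_id %in% s$allele_ids)
      stop("allele id '", wt_id, "' already present; choose another wt_id")
    vaf_sample(c(wt_id, s$allele_ids), c(100, unname(s$vaf)),
               timepoint = s$timepoint,
               weights = if (is.null(s$weights)) NULL
                         else c(1, unname(s$weights)))
  })
}

#' Relax VAF measurements by admitting healthy cells
#'
#' Multiplies every mutated-allele frequency by (100 - x)/100, which is
#' equivalent to artificially adding x percent of healthy cells to the
#' sample. A wild-type root allele, if present, keeps frequency 100. On
#' exact data whose clone frequencies summed to 100 the reconstructed
#' wild-type clone then receives exactly x percent. Relaxation restores
#' feasibility of the true hierarchy when measurement error pushes the
#' founder-clone frequencies to a sum slightly above 100.
#'
#' @inheritParams add_wildtype_root
#' @param x_percent percentage of healthy cells to admit, in [0, 100).
#' @return list of relaxed samples.
#' @export
relax <- function(samples, x_percent, wt_id = "WT") {
  if (!is.numeric(x_percent) || length(x_percent) != 1L ||
      x_percent < 0 || x_percent >= 100)
    stop("'x_percent' must be a scalar in [0, 100)")
  samples <- as_sample_list(samples)
  f <- (100 - x_percent) / 100
  lapply(samples, function(s) {
    v <- s$vaf
    mut <- s$allele_ids != wt_id
    v[mut] <- v[mut] * f
    vaf_sample(s$allele_ids, unname(v), timepoint = s$timepoint,
               weights = unname(s$weights))
  })
}

unify_alleles <- function(samples) {
  alleles <- sort(unique(unlist(lapply(samples, function(s) s$allele_ids))))
  lapply(samples, function(s) {
    missing <- setdiff(alleles, s$allele_ids)
    if (length(missing)) {
      warning("allele(s) ", paste(missing, collapse = ", "),
              " absent at timepoint '", s$timepoint,
              "'; treated as VAF 0", call. = FALSE)
      v <- c(unname(s$vaf), rep(0, length(missing)))
      w <- if (is.null(s$weights)) NULL
           else c(unname(s$weights), rep(1, length(missing)))
      s <- vaf_sample(c(s$allele_ids, missing), v, s$timepoint, w)
    }
    s
  })
}

candidate_cache_get <- function(cache, root, alleles, limit) {
  key <- paste(root, paste(alleles, collapse = ","), sep = "::")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  trees <- enumerate_trees(length(alleles), fixed_root = root,
                           labels = alleles, limit = limit)
  cand <- lapply(trees, function(tr)
    list(tree = tr, A = tree_to_genotype_matrix(tr),
         key = canonical_tree_key(tr)))
  if (!is.null(cache)) cache[[key]] <- cand
  cand
}

fit_tree <- function(cand, samples, tol, total = 100) {
  A <- cand$A
  x_by_tp <- list()
  res_by_tp <- numeric(0)
  exact <- TRUE
  for (s in samples) {
    x <- back_substitute(A, s)
    if (min(x) >= -tol) {
      r <- 0
      # cosmetic cleanup: clamp round-off negatives, preserve the total
      if (any(x < 0)) {
        tot <- sum(x)
        x <- pmax(x, 0)
        if (sum(x) > 0) x <- x * (tot / sum(x))
      }
    } else {
      fit <- constrained_fit(A, s, total = total)
      x <- fit$x
      r <- fit$residual
      exact <- FALSE
    }
    x_by_tp[[s$timepoint]] <- x
    res_by_tp[s$timepoint] <- r
  }
  structure(
    list(tree = cand$tree, key = cand$key,
         x_by_timepoint = x_by_tp,
         residual_by_timepoint = res_by_tp,
         combined_residual = sqrt(sum(res_by_tp^2)),
         exact = exact),
    class = "tree_fit"
  )
}

#' @export
print.tree_fit <- function(x, ...) {
  cat("Tree fit (root ", x$tree$root, "): combined residual ",
      format(x$combined_residual, digits = 6),
      if (x$exact) " [exact]" else "", "\n", sep = "")
  invisible(x)
}

#' Reconstruct all clonal hierarchies compatible with bulk VAF data
#'
#' The end-to-end pipeline: unifies the allele sets across timepoints
#' (absent alleles read as VAF 0, with a warning), optionally normalizes each
#' timepoint so its most abundant mutation is at 100 percent, enumerates
#' every candidate rooted labeled tree, solves each tree's triangular system
#' Ax = b per timepoint by back-substitution, classifies trees whose
#' solutions are non-negative at every timepoint as exact, fits the remaining
#' trees by constrained weighted least squares on the frequency simplex, and
#' ranks all trees by combined residual.
#'
#' In `founder` mode trees are rooted at the most abundant allele (every
#' allele tied at the maximum is tried as root and the enumerations merged).
#' In `wildtype` mode a healthy reference allele is added at 100 percent and
#' all trees are rooted there; `relaxation_percent` then admits artificial
#' healthy cells via [relax()].
#'
#' @param samples a [vaf_sample()] or list of them, one per timepoint.
#' @param mode `"founder"` (root = founding mutation) or `"wildtype"`
#'   (root = healthy reference allele).
#' @param relaxation_percent healthy-cell percentage for [relax()]
#'   (wildtype mode only).
#' @param tol feasibility tolerance for [is_compatible()].
#' @param normalize rescale each timepoint via [normalize_vafs()] (founder
#'   mode). Set to `FALSE` for data that were normalized before an error was
#'   applied, so that the perturbation is not silently erased.
#' @param wt_id reserved wild-type allele identifier.
#' @param ensure_roots additional root labels to enumerate besides the
#'   detected maximal-VAF allele(s) (founder mode). Used by robustness
#'   experiments so that the true hierarchy stays rankable even when noise
#'   displaces its root allele from the maximum.
#' @param limit enumeration limit on the clone count, see [walk_trees()].
#' @param exactness_threshold retained configurable constant for the
#'   residual-based exactness definition ||Ax-b|| < eps; exactness itself is
#'   decided by back-substitution feasibility, which is algebraically exact.
#' @param .cache optional environment for memoising enumerated candidate
#'   trees across repeated calls on the same allele set.
#' @return an object of class `clonal_reconstruction` with elements `mode`,
#'   `relaxation_percent`, `fits` (all trees as `tree_fit`, sorted by
#'   nondecreasing combined residual, ties broken by canonical tree key),
#'   `exact_fits`, `n_trees_enumerated`, `roots`, `timepoints` and `config`.
#' @examples
#' s <- vaf_sample(c("m1", "m2", "m3"), c(100, 60, 30))
#' r <- reconstruct(s)
#' length(r$exact_fits) # 2: chain and star both fit
#' @export
reconstruct <- function(samples, mode = c("founder", "wildtype"),
                        relaxation_percent = 0, tol = 1e-9,
                        normalize = TRUE, wt_id = "WT",
                        ensure_roots = character(0), limit = 8L,
                        exactness_threshold = 1e-15, .cache = NULL) {
  mode <- match.arg(mode)
  samples <- as_sample_list(samples)
  for (s in samples) if (all(s$vaf == 0))
    stop("timepoint '", s$timepoint, "' is all zero")
  samples <- unify_alleles(samples)

  if (mode == "founder") {
    if (relaxation_percent > 0)
      stop("relaxation requires a wild-type root; use mode = \"wildtype\"")
    if (normalize) samples <- lapply(samples, normalize_vafs)
    roots <- sort(unique(c(ensure_roots,
                           unlist(lapply(samples, function(s)
                             s$allele_ids[s$vaf == max(s$vaf)])))))
  } else {
    if (relaxation_percent > 0)
      samples <- relax(samples, relaxation_percent, wt_id = wt_id)
    if (!all(vapply(samples, function(s) wt_id %in% s$allele_ids,
                    logical(1))))
      samples <- add_wildtype_root(samples, wt_id = wt_id)
    roots <- wt_id
  }
  samples <- as_sample_list(samples)
  alleles <- sort(samples[[1L]]$allele_ids)

  fits <- list()
  n_enumerated <- 0L
  for (root in roots) {
    cand <- candidate_cache_get(.cache, root, alleles, limit)
    n_enumerated <- n_enumerated + length(cand)
    fits <- c(fits, lapply(cand, fit_tree, samples = samples, tol = tol))
  }
  resid <- vapply(fits, function(f) f$combined_residual, numeric(1))
  keys <- vapply(fits, function(f) f$key, character(1))
  fits <- fits[order(resid, keys)]

  structure(
    list(mode = mode,
         relaxation_percent = relaxation_percent,
         fits = fits,
         exact_fits = Filter(function(f) f$exact, fits),
         n_trees_enumerated = n_enumerated,
         roots = roots,
         timepoints = names(samples),
         samples = samples,
         config = list(tol = tol, normalize = normalize, wt_id = wt_id,
                       limit = limit,
                       exactness_threshold = exactness_threshold,
                       tie_convention = "ties share the better (minimum) rank")),
    class = "clonal_reconstruction"
  )
}

#' @export
print.clonal_reconstruction <- function(x, ...) {
  cat("Clonal hierarchy reconstruction (", x$mode, " mode",
      if (x$relaxation_percent > 0)
        paste0(", relaxation ", x$relaxation_percent, "%"),
      ")\n", sep = "")
  cat("  timepoints:", paste(x$timepoints, collapse = ", "), "\n")
  cat("  trees enumerated:", x$n_trees_enumerated,
      "(root:", paste(x$roots, collapse = ", "), ")\n")
  cat("  exact fits:", length(x$exact_fits), "\n")
  if (length(x$fits)) {
    best <- x$fits[[1L]]
    cat("  best tree: ", write_newick(best$tree), " residual ",
        format(best$combined_residual, digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' Rank of the true hierarchy within a reconstruction
#'
#' Locates `true_tree` among the ranked fits and summarises how well the
#' reconstruction recovered it. Ties share the better (minimum) rank. A tree
#' is optimal when no other tree has a strictly smaller combined residual,
#' and the optimum is unique when exactly one tree attains the minimum.
#'
#' @param report a `clonal_reconstruction` from [reconstruct()].
#' @param true_tree the known [clonal_tree()] on the same allele set.
#' @param tie_tol residual differences below this count as ties.
#' @return list with `rank`, `is_optimal`, `is_exact`, `optimum_unique`,
#'   `n_exact` and `residual`.
#' @export
rank_summary <- function(report, true_tree, tie_tol = 1e-9) {
  stopifnot(inherits(report, "clonal_reconstruction"),
            inherits(true_tree, "clonal_tree"))
  hit <- which(vapply(report$fits, function(f) same_tree(f$tree, true_tree),
                      logical(1)))
  if (!length(hit))
    stop("true tree not among the enumerated hierarchies; ",
         "check allele labels and root")
  fit <- report$fits[[hit[1L]]]
  resid <- vapply(report$fits, function(f) f$combined_residual, numeric(1))
  rmin <- min(resid)
  list(rank = sum(resid < fit$combined_residual - tie_tol) + 1L,
       is_optimal = fit$combined_residual <= rmin + tie_tol,
       is_exact = fit$exact,
       optimum_unique = sum(resid <= rmin + tie_tol) == 1L,
       n_exact = length(report$exact_fits),
       residual = fit$combined_residual)
}
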