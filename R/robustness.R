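#' Construct a single-cell clone dataset
#'
#' A clones x alleles binary genotype table plus per-clone cell counts (or
#' frequencies), as obtained from single-cell sequencing of the leukemic
#' cells of one timepoint. Serves as ground truth from which bulk VAFs are
#' computed.
#'
#' @param genotypes binary matrix, one row per clone (rownames = clone
#'   labels), one column per allele (colnames = allele ids).
#' @param counts integer cells per clone; exactly one of `counts` /
#'   `frequencies` must be given.
#' @param frequencies per-clone frequencies summing to 1 (exact-frequency
#'   datasets without a finite cell count).
#' @param n_cells total sequenced leukemic cells; defaults to `sum(counts)`.
#' @param timepoint label.
#' @return object of class `single_cell_dataset` with element `f`, the clone
#'   frequency vector used for bulk VAF computation.
#' @export
single_cell_dataset <- function(genotypes, counts = NULL, frequencies = NULL,
                                n_cells = NULL, timepoint = "t1") {
  genotypes <- as.matrix(genotypes)
  names(dimnames(genotypes)) <- NULL
  if (!all(genotypes %in% c(0, 1))) stop("genotypes must be binary")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("clone", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes))) stop("genotype columns must name alleles")
  if (anyDuplicated(apply(genotypes, 1L, paste, collapse = "")))
    stop("genotype rows must be distinct")
  if (is.null(counts) == is.null(frequencies))
    stop("supply exactly one of 'counts' or 'frequencies'")
  if (!is.null(counts)) {
    counts <- as.numeric(counts)
    if (length(counts) != nrow(genotypes) || any(counts < 0))
      stop("'counts' must be non-negative, one per clone")
    if (is.null(n_cells)) n_cells <- sum(counts)
    if (sum(counts) != n_cells) stop("counts must sum to n_cells")
    if (n_cells < 1) stop("dataset must contain at least one cell")
    f <- counts / n_cells
  } else {
    frequencies <- as.numeric(frequencies)
    if (length(frequencies) != nrow(genotypes) || any(frequencies < 0))
      stop("'frequencies' must be non-negative, one per clone")
    if (abs(sum(frequencies) - 1) > 1e-8)
      stop("'frequencies' must sum to 1")
    f <- frequencies / sum(frequencies)
  }
  structure(
    list(genotypes = genotypes,
         counts = counts,
         f = stats::setNames(f, rownames(genotypes)),
         n_cells = n_cells,
         timepoint = as.character(timepoint)),
    class = "single_cell_dataset"
  )
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  cat("Single-cell dataset [", x$timepoint, "]: ", nrow(x$genotypes),
      " clone(s), ", ncol(x$genotypes), " allele(s)",
      if (!is.null(x$n_cells)) paste0(", ", x$n_cells, " cells"),
      "\n", sep = "")
  invisible(x)
}

#' Build the single-cell dataset implied by a clonal tree
#'
#' Each clone's genotype is the ancestor-closure of its node: it carries its
#' own defining mutation plus those of all ancestors.
#'
#' @param tree a [clonal_tree()].
#' @param frequencies per-clone frequencies (named by clone label or in
#'   depth order), summing to 1.
#' @param counts alternative to `frequencies`: integer cell counts.
#' @param timepoint label.
#' @return a [single_cell_dataset()].
#' @export
sc_dataset_from_tree <- function(tree, frequencies = NULL, counts = NULL,
                                 timepoint = "t1") {
  A <- tree_to_genotype_matrix(tree) # alleles x clones
  genotypes <- t(unclass(A))         # clones x alleles
  reord <- function(v) {
    if (!is.null(names(v))) as.numeric(v[rownames(genotypes)]) else v
  }
  single_cell_dataset(genotypes,
                      counts = if (is.null(counts)) NULL else reord(counts),
                      frequencies = if (is.null(frequencies)) NULL
                                    else reord(frequencies),
                      timepoint = timepoint)
}

#' Compute bulk VAFs from a single-cell clone table
#'
#' The bulk frequency of variant allele i is the clone-frequency-weighted
#' sum over the clones that carry it, b_i = sum_j a_ij f_j; for a purely
#' leukemic sample the result is then normalized so the most abundant
#' variant allele is at 100 percent.
#'
#' @param ds a [single_cell_dataset()].
#' @param normalize rescale so `max(b) == 100`.
#' @return a [vaf_sample()] on the percent scale.
#' @export
bulk_vaf_from_sc <- function(ds, normalize = TRUE) {
  stopifnot(inherits(ds, "single_cell_dataset"))
  b <- as.numeric(crossprod(ds$genotypes, ds$f)) * 100
  s <- vaf_sample(colnames(ds$genotypes), b, timepoint = ds$timepoint)
  if (normalize) s <- normalize_vafs(s)
  s
}

#' Multinomial resampling of single-cell clone counts
#'
#' Emulates the sampling error of sequencing only `n_cells` cells: each
#' replicate redraws the clone counts from Multinomial(n_cells, f) with f
#' the observed clone frequencies, keeping the genotypes fixed.
#'
#' @param ds a [single_cell_dataset()] with a finite `n_cells`.
#' @param n_reps number of replicates.
#' @param seed optional integer for reproducibility.
#' @return list of `n_reps` resampled [single_cell_dataset()]s; each
#'   replicate's `f` is its empirical count/n_cells.
#' @export
multinomial_resample <- function(ds, n_reps, seed = NULL) {
  stopifnot(inherits(ds, "single_cell_dataset"))
  if (is.null(ds$n_cells) || ds$n_cells < 1)
    stop("resampling requires a dataset with n_cells >= 1")
  with_seed(seed, {
    draws <- stats::rmultinom(n_reps, size = ds$n_cells, prob = ds$f)
    lapply(seq_len(n_reps), function(r)
      single_cell_dataset(ds$genotypes, counts = draws[, r],
                          n_cells = ds$n_cells, timepoint = ds$timepoint))
  })
}

#' Gaussian perturbation of bulk VAFs
#'
#' Adds independent N(0, sd^2) measurement noise to each allele frequency.
#' Draws that leave the admissible range [0, 100] are excluded: by default
#' the offending allele is redrawn until in range (`"redraw_allele"`), which
#' preserves the replicate count; `"redraw_replicate"` instead redraws the
#' whole replicate vector. Perturbed samples are deliberately NOT
#' re-normalized — losing the exact 100-percent anchor of the founder allele
#' is precisely the error mode that destabilises root identification when
#' the founding clone is small.
#'
#' @param sample a normalized [vaf_sample()].
#' @param sd noise standard deviation in percentage points.
#' @param n_reps number of replicates.
#' @param seed optional integer for reproducibility.
#' @param policy out-of-range handling, see Description.
#' @return list of `n_reps` perturbed [vaf_sample()]s.
#' @export
perturb_vafs <- function(sample, sd, n_reps, seed = NULL,
                         policy = c("redraw_allele", "redraw_replicate")) {
  stopifnot(inherits(sample, "vaf_sample"), sd >= 0)
  policy <- match.arg(policy)
  b <- unname(sample$vaf)
  n <- length(b)
  with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      repeat {
        v <- b + stats::rnorm(n, 0, sd)
        bad <- v < 0 | v > 100
        if (!any(bad)) break
        if (policy == "redraw_allele") {
          while (any(bad)) {
            v[bad] <- b[bad] + stats::rnorm(sum(bad), 0, sd)
            bad <- v < 0 | v > 100
          }
          break
        }
      }
      vaf_sample(sample$allele_ids, v, timepoint = sample$timepoint,
                 weights = unname(sample$weights))
    })
  })
}

#' Robustness of a reconstruction under sampling or measurement error
#'
#' Repeats the full reconstruction on noisy versions of a patient's data and
#' summarises how often the true hierarchy stays exact and optimal. Noise is
#' either `"resample"` (multinomial redraw of the single-cell clone counts,
#' then recomputation of the bulk VAFs) or `"perturb"` (Gaussian error added
#' to the exact bulk VAFs, not re-normalized). Noise is drawn independently
#' per timepoint.
#'
#' @param truth the true [clonal_tree()].
#' @param ds_by_timepoint list of [single_cell_dataset()]s, one per
#'   timepoint.
#' @param noise `"resample"` or `"perturb"`.
#' @param sd perturbation standard deviation (percent), for
#'   `noise = "perturb"`.
#' @param n_reps replicates.
#' @param seed optional integer seed.
#' @param mode,relaxation_percent,tol passed to [reconstruct()].
#' @param wt_id reserved wild-type allele id (wildtype mode).
#' @return object of class `perturbation_summary`: replicate count, the
#'   fractions of replicates in which the truth was optimal / exact and the
#'   optimum unique, the histogram of exact-fit counts, the rank
#'   distribution of the truth, and the per-replicate table.
#' @export
robustness_experiment <- function(truth, ds_by_timepoint,
                                  noise = c("resample", "perturb"),
                                  sd = 0.5, n_reps = 1000, seed = NULL,
                                  mode = "founder", relaxation_percent = 0,
                                  tol = 1e-9, wt_id = "WT") {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "clonal_tree"))
  if (inherits(ds_by_timepoint, "single_cell_dataset"))
    ds_by_timepoint <- list(ds_by_timepoint)
  cache <- new.env(parent = emptyenv())
  exact_bulk <- lapply(ds_by_timepoint, bulk_vaf_from_sc)
  noisy_by_tp <- lapply(seq_along(ds_by_timepoint), function(i) {
    tp_seed <- if (is.null(seed)) NULL else child_seed(seed, i)
    if (noise == "resample") {
      reps <- multinomial_resample(ds_by_timepoint[[i]], n_reps,
                                   seed = tp_seed)
      lapply(reps, bulk_vaf_from_sc)
    } else {
      perturb_vafs(exact_bulk[[i]], sd = sd, n_reps = n_reps,
                   seed = tp_seed)
    }
  })
  per_rep <- data.frame(replicate = seq_len(n_reps), n_compatible = NA_integer_,
                        true_rank = NA_integer_, true_optimal = NA,
                        true_exact = NA, optimum_unique = NA)
  for (r in seq_len(n_reps)) {
    samples <- lapply(noisy_by_tp, `[[`, r)
    rep_report <- reconstruct(samples, mode = mode,
                              relaxation_percent = relaxation_percent,
                              tol = tol, normalize = FALSE, wt_id = wt_id,
                              ensure_roots = if (mode == "founder")
                                truth$root else character(0),
                              .cache = cache)
    rs <- rank_summary(rep_report, truth)
    per_rep$n_compatible[r] <- rs$n_exact
    per_rep$true_rank[r] <- rs$rank
    per_rep$true_optimal[r] <- rs$is_optimal
    per_rep$true_exact[r] <- rs$is_exact
    per_rep$optimum_unique[r] <- rs$optimum_unique
  }
  structure(
    list(n_reps = n_reps,
         noise = noise, sd = if (noise == "perturb") sd else NA_real_,
         frac_true_optimal = mean(per_rep$true_optimal),
         frac_true_exact = mean(per_rep$true_exact),
         frac_optimum_unique = mean(per_rep$optimum_unique),
         histogram_n_compatible = table(per_rep$n_compatible),
         rank_distribution = table(per_rep$true_rank),
         per_replicate = per_rep,
         seed = seed),
    class = "perturbation_summary"
  )
}

#' @export
print.perturbation_summary <- function(x, ...) {
  cat("Robustness summary (", x$noise,
      if (x$noise == "perturb") paste0(", sd = ", x$sd, "%"),
      "), ", x$n_reps, " replicates\n", sep = "")
  cat(sprintf("  truth optimal: %.1f%%  truth exact: %.1f%%  optimum unique: %.1f%%\n",
              100 * x$frac_true_optimal, 100 * x$frac_true_exact,
              100 * x$frac_optimum_unique))
  cat("  exact-fit count histogram:\n")
  print(x$histogram_n_compatible)
  invisible(x)
}

#' Exhaustive uniqueness experiment on small trees
#'
#' For every fixed-root topology on `n` clones, draws many clone-frequency
#' vectors uniformly from the simplex (independently per timepoint),
#' computes the exact bulk VAFs they imply, and counts how many of the
#' topologies are compatible (non-negative back-substitution solution at
#' every timepoint). The distribution of compatible-tree counts per
#' generating topology quantifies how often exact bulk data pin down the
#' hierarchy uniquely, and how much a second timepoint helps.
#'
#' @param n clone count.
#' @param n_datasets frequency draws per generating topology.
#' @param timepoints 1 or 2 independent timepoints per draw.
#' @param seed optional integer seed.
#' @param tol feasibility tolerance.
#' @return object of class `uniqueness_table`: the generating topologies
#'   (Newick), a `counts` matrix (topology x dataset) of compatible-tree
#'   counts, and per-topology count distributions.
#' @export
uniqueness_experiment <- function(n, n_datasets = 10000, timepoints = 2,
                                  seed = NULL, tol = 1e-9) {
  stopifnot(timepoints %in% c(1, 2))
  trees <- enumerate_trees(n, fixed_root = "m1")
  mats <- lapply(trees, tree_to_genotype_matrix)
  n_top <- length(trees)
  counts <- matrix(0L, n_top, n_datasets)
  with_seed(seed, {
    for (g in seq_len(n_top)) {
      compat_all <- matrix(TRUE, n_top, n_datasets)
      for (tp in seq_len(timepoints)) {
        # uniform simplex draws (flat Dirichlet), columns are datasets
        X <- matrix(stats::rexp(n * n_datasets), n, n_datasets)
        X <- sweep(X, 2L, colSums(X), "/") * 100
        B <- unclass(mats[[g]]) %*% X # rows follow mats[[g]]'s allele order
        rownames(B) <- rownames(mats[[g]])
        for (cnd in seq_len(n_top)) {
          Bc <- B[rownames(mats[[cnd]]), , drop = FALSE]
          Xc <- backsolve(mats[[cnd]], Bc)
          compat_all[cnd, ] <- compat_all[cnd, ] &
            (colSums(Xc < -tol) == 0L)
        }
      }
      counts[g, ] <- colSums(compat_all)
    }
  })
  distributions <- lapply(seq_len(n_top), function(g)
    table(factor(counts[g, ], levels = seq_len(n_top))))
  names(distributions) <- vapply(trees, write_newick, character(1))
  structure(
    list(n = n, n_datasets = n_datasets, timepoints = timepoints,
         topologies = trees, counts = counts,
         distributions = distributions,
         frac_at_most_two = mean(counts <= 2L),
         frac_unique = mean(counts == 1L),
         seed = seed),
    class = "uniqueness_table"
  )
}

#' @export
print.uniqueness_table <- function(x, ...) {
  cat("Uniqueness experiment: n = ", x$n, ", ", x$n_datasets,
      " datasets/topology, ", x$timepoints, " timepoint(s)\n", sep = "")
  cat(sprintf("  unique fit: %.1f%%   at most two fits: %.1f%%\n",
              100 * x$frac_unique, 100 * x$frac_at_most_two))
  invisible(x)
}
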