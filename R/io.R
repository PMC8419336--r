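read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a bulk VAF table
#'
#' Expects columns `mutation_id`, `timepoint` and `vaf_percent` (percent
#' scale, 0-100); optional `ci_low` / `ci_high` confidence bounds are turned
#' into least-squares weights 1 / half-width. TSV or CSV by file extension.
#' Unknown columns are preserved as an `extra` attribute.
#'
#' @param path file path.
#' @return named list of [vaf_sample()]s, one per timepoint, in file order.
#' @export
read_vaf_table <- function(path) {
  df <- read_table_auto(path)
  need <- c("mutation_id", "timepoint", "vaf_percent")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("VAF table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(is.na(df$vaf_percent) | df$vaf_percent < 0 |
                 df$vaf_percent > 100)
  if (length(bad))
    stop("vaf_percent outside [0, 100] at data row(s) ",
         paste(bad, collapse = ", "), " of ", path,
         " (percentages expected, not fractions)")
  has_ci <- all(c("ci_low", "ci_high") %in% names(df))
  tps <- unique(df$timepoint)
  samples <- lapply(tps, function(tp) {
    sub <- df[df$timepoint == tp, , drop = FALSE]
    w <- NULL
    if (has_ci && !anyNA(sub$ci_low) && !anyNA(sub$ci_high)) {
      half <- (sub$ci_high - sub$ci_low) / 2
      if (any(half <= 0))
        stop("non-positive confidence interval width at timepoint ", tp)
      w <- 1 / half
    }
    s <- vaf_sample(sub$mutation_id, sub$vaf_percent, timepoint = tp,
                    weights = w)
    extra_cols <- setdiff(names(sub), c(need, "ci_low", "ci_high"))
    if (length(extra_cols)) attr(s, "extra") <- sub[, extra_cols,
                                                    drop = FALSE]
    s
  })
  stats::setNames(samples, tps)
}

#' Write a bulk VAF table
#'
#' Inverse of [read_vaf_table()]; values round-trip at full precision.
#'
#' @param samples a [vaf_sample()] or list of them.
#' @param path output path (.tsv or .csv).
#' @return `path`, invisibly.
#' @export
write_vaf_table <- function(samples, path) {
  samples <- as_sample_list(samples)
  rows <- do.call(rbind, lapply(samples, function(s) {
    d <- data.frame(mutation_id = s$allele_ids, timepoint = s$timepoint,
                    vaf_percent = unname(s$vaf))
    if (!is.null(s$weights)) {
      half <- 1 / unname(s$weights)
      d$ci_low <- unname(s$vaf) - half
      d$ci_high <- unname(s$vaf) + half
    }
    d
  }))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a single-cell clone table
#'
#' Expects one row per clone with a `timepoint` column, a `count` column
#' (cells per clone) and one binary column per allele; an optional `clone`
#' column names the clones.
#'
#' @param path file path (TSV or CSV by extension).
#' @return named list of [single_cell_dataset()]s, one per timepoint.
#' @export
read_sc_table <- function(path) {
  df <- read_table_auto(path)
  if (!all(c("timepoint", "count") %in% names(df)))
    stop("single-cell table ", path,
         " must have 'timepoint' and 'count' columns")
  allele_cols <- setdiff(names(df), c("timepoint", "count", "clone"))
  if (!length(allele_cols)) stop("no allele columns found in ", path)
  gm <- as.matrix(df[, allele_cols, drop = FALSE])
  if (!all(gm %in% c(0, 1)))
    stop("allele columns of ", path, " must be binary 0/1")
  tps <- unique(df$timepoint)
  out <- lapply(tps, function(tp) {
    sel <- df$timepoint == tp
    g <- gm[sel, , drop = FALSE]
    rownames(g) <- if ("clone" %in% names(df)) df$clone[sel]
                   else paste0("clone", seq_len(sum(sel)))
    single_cell_dataset(g, counts = df$count[sel], timepoint = tp)
  })
  stats::setNames(out, tps)
}

#' Write a single-cell clone table
#'
#' @param datasets a [single_cell_dataset()] or list of them.
#' @param path output path (.tsv or .csv).
#' @return `path`, invisibly.
#' @export
write_sc_table <- function(datasets, path) {
  if (inherits(datasets, "single_cell_dataset")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(ds) {
    if (is.null(ds$counts))
      stop("cannot serialise an exact-frequency dataset; supply counts")
    data.frame(clone = rownames(ds$genotypes), timepoint = ds$timepoint,
               count = ds$counts, ds$genotypes, check.names = FALSE)
  }))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

fit_to_list <- function(fit, rank) {
  tree <- fit$tree
  list(rank = rank,
       root = tree$root,
       parent = as.list(tree$parent[!is.na(tree$parent)]),
       newick = write_newick(tree),
       exact = fit$exact,
       combined_residual = fit$combined_residual,
       residual_by_timepoint = as.list(fit$residual_by_timepoint),
       x_by_timepoint = lapply(fit$x_by_timepoint, as.list))
}

#' Write a reconstruction report as JSON
#'
#' Serialises a [reconstruct()] result (schema_version 1): mode, relaxation,
#' enumeration count, and every tree as a parent map with per-timepoint
#' clone frequencies, residuals, exactness flag and rank (ties share the
#' better rank).
#'
#' @param report a `clonal_reconstruction`.
#' @param path output JSON path.
#' @param top_k keep only the `top_k` best trees (default all).
#' @param newick_dir optional directory; one Newick file per reported tree
#'   (`tree_<rank>.nwk`, exact trees additionally flagged in the name).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, top_k = NULL, newick_dir = NULL) {
  stopifnot(inherits(report, "clonal_reconstruction"))
  resid <- vapply(report$fits, function(f) f$combined_residual, numeric(1))
  ranks <- vapply(seq_along(resid), function(i)
    sum(resid < resid[i] - report$config$tol) + 1L, integer(1))
  keep <- seq_along(report$fits)
  if (!is.null(top_k)) keep <- keep[seq_len(min(top_k, length(keep)))]
  obj <- list(
    schema_version = 1L,
    mode = report$mode,
    relaxation_percent = report$relaxation_percent,
    roots = report$roots,
    timepoints = report$timepoints,
    n_trees_enumerated = report$n_trees_enumerated,
    n_exact = length(report$exact_fits),
    config = report$config,
    trees = lapply(keep, function(i) fit_to_list(report$fits[[i]],
                                                 ranks[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(newick_dir)) {
    dir.create(newick_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in keep) {
      f <- report$fits[[i]]
      fn <- sprintf("tree_%03d%s.nwk", i, if (f$exact) "_exact" else "")
      write_newick(f$tree, frequencies = f$x_by_timepoint,
                   file = file.path(newick_dir, fn))
    }
  }
  invisible(path)
}

#' Write a robustness summary as JSON (plus optional per-replicate TSV)
#'
#' @param summary a `perturbation_summary` from [robustness_experiment()].
#' @param path output JSON path.
#' @param replicates_path optional TSV path for the per-replicate table
#'   (replicate, n_compatible, true_rank, true_optimal, true_exact,
#'   optimum_unique).
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, replicates_path = NULL) {
  stopifnot(inherits(summary, "perturbation_summary"))
  obj <- list(
    schema_version = 1L,
    noise = summary$noise, sd = summary$sd,
    n_reps = summary$n_reps, seed = summary$seed,
    frac_true_optimal = summary$frac_true_optimal,
    frac_true_exact = summary$frac_true_exact,
    frac_optimum_unique = summary$frac_optimum_unique,
    histogram_n_compatible = as.list(
      stats::setNames(as.integer(summary$histogram_n_compatible),
                      names(summary$histogram_n_compatible))),
    rank_distribution = as.list(
      stats::setNames(as.integer(summary$rank_distribution),
                      names(summary$rank_distribution)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(replicates_path))
    utils::write.table(summary$per_replicate, replicates_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}
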