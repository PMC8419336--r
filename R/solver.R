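#' Construct a bulk VAF sample
#'
#' Holds the measured bulk variant allele frequencies of one timepoint, on the
#' percent scale (0-100). Optional positive weights (the diagonal of the
#' weighting matrix W, typically 1 / half-width of each allele's confidence
#' interval) feed into the weighted least-squares fit.
#'
#' @param allele_ids character vector of allele (mutation) identifiers.
#' @param vaf numeric frequencies in percent, aligned to `allele_ids`.
#' @param timepoint label such as "diagnosis" or "relapse".
#' @param weights optional strictly positive weights aligned to `allele_ids`.
#' @return an object of class `vaf_sample`.
#' @export
vaf_sample <- function(allele_ids, vaf, timepoint = "t1", weights = NULL) {
  allele_ids <- as.character(allele_ids)
  vaf <- as.numeric(vaf)
  if (length(allele_ids) == 0L) stop("sample must contain at least one allele")
  if (anyDuplicated(allele_ids)) stop("duplicate allele identifiers")
  if (length(vaf) != length(allele_ids))
    stop("'vaf' and 'allele_ids' lengths differ")
  # tolerate float round-off at the boundaries (e.g. 100 + 1e-14 after
  # normalization), reject anything genuinely out of range
  eps <- 1e-9
  if (anyNA(vaf) || any(vaf < -eps) || any(vaf > 100 + eps))
    stop("VAFs must lie in [0, 100] percent; got ",
         paste(format(vaf[is.na(vaf) | vaf < -eps | vaf > 100 + eps]),
               collapse = ", "))
  vaf <- pmin(pmax(vaf, 0), 100)
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(allele_ids) || anyNA(weights) ||
        any(weights <= 0))
      stop("weights must be strictly positive and aligned to allele_ids")
    weights <- stats::setNames(weights, allele_ids)
  }
  structure(
    list(allele_ids = allele_ids,
         vaf = stats::setNames(vaf, allele_ids),
         timepoint = as.character(timepoint),
         weights = weights),
    class = "vaf_sample"
  )
}

#' @export
print.vaf_sample <- function(x, ...) {
  cat("VAF sample [", x$timepoint, "], ", length(x$allele_ids),
      " allele(s)\n", sep = "")
  print(round(x$vaf, 3))
  invisible(x)
}

align_b <- function(A, b) {
  vec <- if (inherits(b, "vaf_sample")) b$vaf else b
  if (is.null(names(vec))) {
    if (length(vec) != nrow(A)) stop("dimension mismatch: b has ",
                                     length(vec), " entries, A has ",
                                     nrow(A), " rows")
    return(as.numeric(vec))
  }
  missing <- setdiff(rownames(A), names(vec))
  if (length(missing))
    stop("alleles absent from b: ", paste(missing, collapse = ", "))
  as.numeric(vec[rownames(A)])
}

align_weights <- function(A, b) {
  if (inherits(b, "vaf_sample") && !is.null(b$weights))
    as.numeric(b$weights[rownames(A)])
  else rep(1, nrow(A))
}

#' Solve the triangular clone-frequency system
#'
#' Solves Ax = b for the clone frequencies x by back-substitution:
#' x_n = b_n and x_j = b_j - sum_{k > j} a_jk x_k. Because A is unit upper
#' triangular (determinant 1) the solution is unique.
#'
#' @param A a `genotype_matrix` (or any unit upper triangular matrix with
#'   allele rownames).
#' @param b a [vaf_sample()] or a numeric vector (named by allele, or in row
#'   order of A).
#' @return named numeric vector of clone frequencies, in the clone (column)
#'   order of A; components may be negative when b is incompatible with the
#'   tree.
#' @export
back_substitute <- function(A, b) {
  bv <- align_b(A, b)
  stats::setNames(backsolve(A, bv), colnames(A))
}

#' Test biological compatibility of a sample with a hierarchy
#'
#' A VAF vector b is compatible with the clonal hierarchy represented by A
#' when Ax = b has a componentwise non-negative solution, i.e. the bulk
#' frequencies can be produced by mixing the tree's clones in non-negative
#' proportions.
#'
#' @inheritParams back_substitute
#' @param tol non-negative slack: components down to `-tol` still count as
#'   feasible (floating-point guard).
#' @return logical scalar.
#' @export
is_compatible <- function(A, b, tol = 1e-9) {
  min(back_substitute(A, b)) >= -tol
}

#' Constrained weighted least-squares fit of a hierarchy to a sample
#'
#' For data incompatible with a tree (typically due to measurement error),
#' finds the clone frequencies minimising ||W(Ax - b)||_2 subject to
#' x_i >= 0 and sum(x) = `total`. This is a convex quadratic program
#' (D = A'W'WA is positive definite since det(A) = 1 and W > 0), so the
#' global optimum is attained; it is solved with the dual active-set method
#' of Goldfarb and Idnani via [quadprog::solve.QP()].
#'
#' @inheritParams back_substitute
#' @param total the simplex total, 100 for percent data.
#' @return list with `x` (named solution) and `residual`
#'   (||W(Ax - b)||_2 at the optimum).
#' @export
constrained_fit <- function(A, b, total = 100) {
  bv <- align_b(A, b)
  w <- align_weights(A, b)
  n <- nrow(A)
  M <- w * unclass(A) # W %*% A, W diagonal
  Dmat <- crossprod(M)
  dvec <- crossprod(M, w * bv)
  Amat <- cbind(rep(1, n), diag(n))
  bvec <- c(total, rep(0, n))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1L),
    error = function(e) stop("QP solve failed for genotype matrix [",
                             paste(colnames(A), collapse = ","), "]: ",
                             conditionMessage(e))
  )
  x <- pmax(sol$solution, 0)
  resid <- sqrt(sum((w * (unclass(A) %*% x - bv))^2))
  list(x = stats::setNames(x, colnames(A)), residual = resid)
}

#' Spectral condition number of a genotype matrix
#'
#' Ratio of the largest to the smallest singular value (l2-norm condition
#' number). It bounds how strongly VAF measurement errors are amplified into
#' clone-frequency errors: ||dx||/||x|| <= kappa(A) ||db||/||b||.
#'
#' @param A a `genotype_matrix`.
#' @return scalar >= 1.
#' @export
condition_number <- function(A) {
  s <- svd(unclass(A), nu = 0, nv = 0)$d
  max(s) / min(s)
}

#' Sensitivity of reconstructed clone frequencies to VAF perturbations
#'
#' Returns x - x' for the back-substitution solutions under b and b'. By
#' Cramer's rule (det A = 1) each difference equals the determinant of A with
#' the corresponding column replaced by b - b'; in particular the last
#' component satisfies x_n - x_n' = b_n - b_n' exactly.
#'
#' @inheritParams back_substitute
#' @param b_prime second sample, aligned to the same alleles.
#' @return named numeric vector x - x'.
#' @export
solution_sensitivity <- function(A, b, b_prime) {
  back_substitute(A, b) - back_substitute(A, b_prime)
}
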