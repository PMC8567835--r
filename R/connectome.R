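#' Structural connectome
#'
#' A structural connectome is a symmetric region-by-region matrix whose
#' entry (i, j) is the mean streamline (fiber) length between regions i and
#' j, in millimeters. A zero off-diagonal entry means "no structural
#' connection"; the diagonal is zero by convention. The matrix is used
#' unthresholded and unbinarized: fiber length is the edge weight that
#' shortest-path computation minimizes directly.
#'
#' @param lengths Numeric N x N matrix of mean streamline lengths (mm).
#' @param region_ids Character vector of region identifiers, in the order of
#'   the matrix rows. Defaults to the rownames of `lengths`, or `R1..RN`.
#' @param tol Symmetry tolerance (absolute), default `1e-9`.
#'
#' @return An object of class `structural_connectome`: a list with elements
#'   `lengths` (the validated matrix, dimnames set to the region ids) and
#'   `region_ids`.
#' @examples
#' m <- matrix(c(0, 10, 0, 10, 0, 20, 0, 20, 0), 3, 3)
#' sc <- structural_connectome(m, c("A", "B", "C"))
#' sc
#' @export
structural_connectome <- function(lengths, region_ids = NULL, tol = 1e-9) {
  lengths <- as.matrix(lengths)
  if (!is.numeric(lengths) || nrow(lengths) != ncol(lengths)) {
    abort("`lengths` must be a square numeric matrix.")
  }
  n <- nrow(lengths)
  if (is.null(region_ids)) {
    region_ids <- rownames(lengths)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != n || anyDuplicated(region_ids)) {
    abort("`region_ids` must be unique and match the matrix dimension.")
  }
  if (anyNA(lengths) || any(!is.finite(lengths))) {
    abort("structural connectome contains non-finite entries.")
  }
  if (any(lengths < 0)) {
    bad <- which(lengths < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "structural connectome has a negative length at (%d, %d); lengths are millimeters and must be >= 0.",
      bad[1], bad[2]
    ))
  }
  if (max(abs(lengths - t(lengths))) > tol) {
    abort(sprintf(
      "structural connectome is asymmetric beyond tolerance %g.", tol
    ))
  }
  if (any(diag(lengths) != 0)) {
    abort("structural connectome must have a zero diagonal.")
  }
  lengths <- (lengths + t(lengths)) / 2  # exact symmetry
  dimnames(lengths) <- list(region_ids, region_ids)
  structure(list(lengths = lengths, region_ids = region_ids),
            class = "structural_connectome")
}

#' Functional connectome
#'
#' A functional connectome here is a symmetric region-by-region matrix of
#' pairwise mutual information (MI), in bits, estimated from regional BOLD
#' time series. The diagonal stores each region's binned entropy H(i) (the
#' value of MI(i; i)); it is excluded from all path and strength
#' computations.
#'
#' @param mi Numeric N x N symmetric matrix of MI values (bits).
#' @param region_ids Character region identifiers (defaults as in
#'   [structural_connectome()]).
#' @param binning The [binning_scheme()] used to estimate the matrix, or
#'   `NULL` when unknown (e.g. a precomputed matrix read from disk).
#' @param tol Symmetry tolerance, default `1e-9`.
#'
#' @return An object of class `functional_connectome`: list with `mi`,
#'   `region_ids`, `binning`.
#' @export
functional_connectome <- function(mi, region_ids = NULL, binning = NULL,
                                  tol = 1e-9) {
  mi <- as.matrix(mi)
  if (!is.numeric(mi) || nrow(mi) != ncol(mi)) {
    abort("`mi` must be a square numeric matrix.")
  }
  n <- nrow(mi)
  if (is.null(region_ids)) {
    region_ids <- rownames(mi)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != n || anyDuplicated(region_ids)) {
    abort("`region_ids` must be unique and match the matrix dimension.")
  }
  if (anyNA(mi) || any(!is.finite(mi))) {
    abort("functional connectome contains non-finite entries.")
  }
  off <- mi[row(mi) != col(mi)]
  if (any(off < 0)) {
    abort("mutual information must be >= 0 off the diagonal.")
  }
  if (max(abs(mi - t(mi))) > tol) {
    abort(sprintf("functional connectome is asymmetric beyond tolerance %g.",
                  tol))
  }
  mi <- (mi + t(mi)) / 2
  dimnames(mi) <- list(region_ids, region_ids)
  structure(list(mi = mi, region_ids = region_ids, binning = binning),
            class = "functional_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- length(x$region_ids)
  ne <- sum(x$lengths[upper.tri(x$lengths)] > 0)
  cat(sprintf(
    "<structural_connectome> %d regions, %d edges, lengths %.1f-%.1f mm\n",
    n, ne,
    if (ne) min(x$lengths[x$lengths > 0]) else NA_real_,
    if (ne) max(x$lengths) else NA_real_
  ))
  invisible(x)
}

#' @export
print.functional_connectome <- function(x, ...) {
  n <- length(x$region_ids)
  off <- x$mi[row(x$mi) != col(x$mi)]
  cat(sprintf(
    "<functional_connectome> %d regions, MI %.3f-%.3f bits%s\n",
    n, min(off), max(off),
    if (is.null(x$binning)) "" else
      sprintf(" (bin width %g over [%g, %g])",
              x$binning$bin_width, x$binning$range[1], x$binning$range[2])
  ))
  invisible(x)
}

n_regions <- function(x) length(x$region_ids)

check_same_regions <- function(a, b, what = "objects") {
  if (!identical(a$region_ids, b$region_ids)) {
    abort(sprintf("%s are defined on different region sets.", what))
  }
  invisible(TRUE)
}
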