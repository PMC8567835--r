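#' Uniform binning scheme for mutual-information estimation
#'
#' Defines the discretization applied to z-scored BOLD signals before the
#' joint-histogram (plug-in) MI estimate. The defaults follow the standard
#' choice for binned MI connectomes: bins of width 0.5 SD spanning
#' \[-3.5, 3.5\] z-score units, i.e. 14 bins. Values outside the range are
#' clipped into the boundary bins, so the sample count is preserved. When
#' the width does not divide the span exactly (e.g. 0.75 over a span of 7),
#' the number of bins is rounded up and the last bin is truncated at the
#' upper range limit.
#'
#' @param bin_width Bin width in z-score units (> 0). Default `0.5`.
#' @param range Length-2 numeric, lower and upper limit in z-score units.
#'   Default `c(-3.5, 3.5)`.
#' @return An object of class `binning_scheme` with fields `bin_width`,
#'   `range`, `n_bins`.
#' @examples
#' binning_scheme()          # 14 bins
#' binning_scheme(1)         # 7 bins
#' @export
binning_scheme <- function(bin_width = 0.5, range = c(-3.5, 3.5)) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    abort("`bin_width` must be a single positive number.")
  }
  if (length(range) != 2 || range[1] >= range[2]) {
    abort("`range` must be c(lower, upper) with lower < upper.")
  }
  span <- range[2] - range[1]
  n_bins <- as.integer(ceiling(span / bin_width - 1e-9))
  structure(list(bin_width = bin_width, range = as.numeric(range),
                 n_bins = n_bins),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> width %g over [%g, %g] (%d bins)\n",
              x$bin_width, x$range[1], x$range[2], x$n_bins))
  invisible(x)
}

same_binning <- function(a, b) {
  !is.null(a) && !is.null(b) &&
    isTRUE(all.equal(a$bin_width, b$bin_width)) &&
    isTRUE(all.equal(a$range, b$range))
}

#' Z-score regional time series
#'
#' Standardizes each region's time course to mean 0 and SD 1 using the
#' population SD (divide by T, not T-1); the convention is fixed so that
#' downstream binning is reproducible bit-for-bit. Idempotent on already
#' z-scored input.
#'
#' @param ts Numeric N x T matrix, one region per row.
#' @return Matrix of the same shape, rownames preserved.
#' @export
zscore_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 2) abort("time series must have T >= 2 timepoints.")
  if (anyNA(ts)) abort("time series contains missing values.")
  mu <- rowMeans(ts)
  centred <- ts - mu
  s <- sqrt(rowMeans(centred^2))
  if (any(s == 0)) {
    bad <- which(s == 0)[1]
    id <- rownames(ts)[bad]
    abort(sprintf("region %s has a constant time course (zero variance).",
                  if (is.null(id)) as.character(bad) else id))
  }
  centred / s
}

#' Discretize z-scored time series into uniform bins
#'
#' Bin edges are half-open `[lo, hi)` with the last bin closed; values
#' outside the range are clipped into the boundary bins. With the default
#' scheme, a value of exactly -3.5 maps to code 0, a value of 0 maps to
#' code 7 (bin `[0, 0.5)`), and any value above 3.5 maps to code 13.
#'
#' @param ts Z-scored N x T matrix (see [zscore_timeseries()]).
#' @param scheme A [binning_scheme()].
#' @return Integer matrix of codes in `0 .. n_bins - 1`.
#' @export
discretize_timeseries <- function(ts, scheme = binning_scheme()) {
  ts <- as.matrix(ts)
  if (anyNA(ts) || any(!is.finite(ts))) {
    abort("time series contains NaN/NA samples; cannot discretize.")
  }
  codes <- floor((ts - scheme$range[1]) / scheme$bin_width)
  codes[codes < 0] <- 0
  codes[codes > scheme$n_bins - 1] <- scheme$n_bins - 1
  mode(codes) <- "integer"
  codes
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_pair_codes <- function(ci, cj, n_bins) {
  tt <- length(ci)
  joint <- tabulate(ci * n_bins + cj + 1L, nbins = n_bins * n_bins) / tt
  pi_ <- tabulate(ci + 1L, nbins = n_bins) / tt
  pj <- tabulate(cj + 1L, nbins = n_bins) / tt
  # H(X) + H(Y) - H(X,Y): guarantees MI(X;X) == H(X) exactly in floating
  # arithmetic and is algebraically identical to the plug-in sum over
  # occupied joint cells
  max(0, entropy_bits(pi_) + entropy_bits(pj) - entropy_bits(joint))
}

#' Pairwise mutual information from discretized time series
#'
#' Plug-in (maximum-likelihood) estimator on the joint histogram:
#' `MI(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` over occupied cells,
#' computed as `H(X) + H(Y) - H(X,Y)` in bits. No bias correction is
#' applied. The matrix is symmetric by construction; the diagonal stores
#' each region's binned entropy `H(i)`.
#'
#' @param codes Integer code matrix from [discretize_timeseries()].
#' @param scheme The [binning_scheme()] that produced the codes.
#' @param region_ids Optional region identifiers.
#' @return A [functional_connectome()].
#' @export
pairwise_mi <- function(codes, scheme = binning_scheme(), region_ids = NULL) {
  codes <- as.matrix(codes)
  if (ncol(codes) < 2) abort("need T >= 2 samples to estimate MI.")
  n <- nrow(codes)
  b <- scheme$n_bins
  if (any(codes < 0L | codes >= b)) {
    abort("codes outside 0..n_bins-1; did you use discretize_timeseries()?")
  }
  mi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- mi_pair_codes(codes[i, ], codes[j, ], b)
      mi[i, j] <- v
      mi[j, i] <- v
    }
  }
  if (is.null(region_ids)) region_ids <- rownames(codes)
  functional_connectome(mi, region_ids, binning = scheme)
}

#' Estimate an MI functional connectome from raw regional time series
#'
#' Convenience pipeline: [zscore_timeseries()] then
#' [discretize_timeseries()] then [pairwise_mi()].
#'
#' @inheritParams zscore_timeseries
#' @inheritParams discretize_timeseries
#' @return A [functional_connectome()].
#' @export
mi_connectome <- function(ts, scheme = binning_scheme()) {
  z <- zscore_timeseries(ts)
  pairwise_mi(discretize_timeseries(z, scheme), scheme,
              region_ids = rownames(ts))
}

#' Average functional connectomes across acquisition runs
#'
#' Element-wise mean of two MI connectomes estimated with the same binning
#' (e.g. the LR and RL phase-encoding runs of one session), improving
#' signal-to-noise.
#'
#' @param fc_a,fc_b [functional_connectome()] objects with identical
#'   regions and binning.
#' @return A [functional_connectome()].
#' @export
average_runs <- function(fc_a, fc_b) {
  check_same_regions(fc_a, fc_b, "functional connectomes")
  if (!is.null(fc_a$binning) || !is.null(fc_b$binning)) {
    if (!same_binning(fc_a$binning, fc_b$binning)) {
      abort("cannot average runs estimated with different binning schemes.")
    }
  }
  functional_connectome((fc_a$mi + fc_b$mi) / 2, fc_a$region_ids,
                        binning = fc_a$binning)
}

#' Sensitivity of the MI connectome to the bin width
#'
#' Re-estimates the functional connectome for several bin widths over a
#' common range and summarizes agreement as the Pearson correlation between
#' upper-triangle MI values of every pair of widths.
#'
#' @param ts Raw N x T regional time series.
#' @param widths Numeric vector of bin widths; default `c(0.5, 0.75, 1, 2)`.
#' @param range Z-score range, default `c(-3.5, 3.5)`.
#' @return List with `connectomes` (one [functional_connectome()] per
#'   width, named by width) and `agreement` (tibble with columns `width_a`,
#'   `width_b`, `correlation`).
#' @export
bin_sensitivity <- function(ts, widths = c(0.5, 0.75, 1, 2),
                            range = c(-3.5, 3.5)) {
  if (!length(widths)) abort("need at least one width.")
  z <- zscore_timeseries(ts)
  fcs <- lapply(widths, function(w) {
    sch <- binning_scheme(w, range)
    pairwise_mi(discretize_timeseries(z, sch), sch, region_ids = rownames(ts))
  })
  names(fcs) <- as.character(widths)
  ut <- lapply(fcs, function(f) f$mi[upper.tri(f$mi)])
  grid <- expand.grid(a = seq_along(widths), b = seq_along(widths))
  agreement <- tibble(
    width_a = widths[grid$a],
    width_b = widths[grid$b],
    correlation = mapply(function(a, b) {
      if (a == b) return(1)
      if (sd(ut[[a]]) == 0 || sd(ut[[b]]) == 0) return(NA_real_)
      cor(ut[[a]], ut[[b]])
    }, grid$a, grid$b)
  )
  list(connectomes = fcs, agreement = agreement)
}
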