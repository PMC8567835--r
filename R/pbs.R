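#' Structurally masked nodal MI strength
#'
#' For each region i, `W_i` sums the mutual information of i with every
#' region j to which i is structurally connected (`SC(i, j) > 0`, j != i).
#' Functional couplings without a supporting white-matter edge do not
#' contribute: under the framework's assumptions, direct communication
#' requires a structural connection.
#'
#' @param fc A [functional_connectome()].
#' @param sc A [structural_connectome()] on the same regions.
#' @return Tibble with columns `region_index`, `region`, `strength` (bits).
#' @export
structural_strength <- function(fc, sc) {
  check_same_regions(fc, sc, "connectomes")
  w <- strength_vector(fc, sc)
  tibble(region_index = seq_along(w), region = fc$region_ids,
         strength = unname(w))
}

strength_vector <- function(fc, sc) {
  mask <- sc$lengths > 0
  diag(mask) <- FALSE
  w <- rowSums(fc$mi * mask)
  names(w) <- fc$region_ids
  w
}

#' Path broadcasting strength of a single path
#'
#' The path broadcasting strength (PBS) is the search information of the
#' structural geodesic evaluated on functional weights: with
#' `MI_i` the MI of the edge leaving node i along the path and `W_i` the
#' structurally masked nodal strength of i,
#' `PBS_raw = -log2( prod_{i in (S, K1, ..., Km)} MI_i / W_i )`
#' in bits, and the reported PBS is `PBS_raw / |path|` in bits/mm, where
#' `|path|` is the total fiber length, removing the bias toward longer
#' paths. Low PBS means the signal flows specifically along the path
#' (routing); high PBS means it also spreads through adjacent edges
#' (broadcasting). PBS is defined for single-edge (direct) paths.
#'
#' With `exclude_incoming = TRUE` the classical search-information
#' convention is used instead: at intermediate nodes the denominator is
#' `W_i` minus the MI of the arrival edge. The default keeps the full
#' `W_i`.
#'
#' @param path Node sequence (indices or region names), source first.
#' @param fc A [functional_connectome()].
#' @param sc A [structural_connectome()] (used for the masked strengths
#'   and the mm length); alternatively pass precomputed `strengths`.
#' @param strengths Optional named strength vector (as from
#'   [structural_strength()]'s `strength` column, in region order).
#' @param length_mm Optional precomputed total path length; computed from
#'   `sc` when missing.
#' @param exclude_incoming Use the classical convention (default `FALSE`).
#' @return Named numeric: `raw` (bits) and `per_mm` (bits/mm). `Inf` when
#'   a path edge has zero MI.
#' @examples
#' fx <- toy_fixture()
#' compute_pbs(c(1, 2, 3, 5), fx$fc, fx$sc)
#' @export
compute_pbs <- function(path, fc, sc = NULL, strengths = NULL,
                        length_mm = NULL, exclude_incoming = FALSE) {
  if (is.character(path)) {
    path <- vapply(path, resolve_region, 1L, region_ids = fc$region_ids)
  }
  if (length(path) < 2) abort("a path needs at least one edge.")
  if (is.null(strengths)) {
    if (is.null(sc)) abort("provide `sc` or precomputed `strengths`.")
    strengths <- strength_vector(fc, sc)
  }
  if (is.null(length_mm)) {
    if (is.null(sc)) abort("provide `sc` or `length_mm`.")
    steps <- cbind(path[-length(path)], path[-1])
    len <- sc$lengths[steps]
    if (any(len <= 0)) {
      abort("path traverses a structurally absent edge.")
    }
    length_mm <- sum(len)
  }
  from <- path[-length(path)]
  to <- path[-1]
  edge_mi <- fc$mi[cbind(from, to)]
  denom <- strengths[from]
  if (exclude_incoming && length(path) > 2) {
    # at intermediate nodes, discount the arrival edge
    inter <- seq(2, length(path) - 1)
    denom[inter] <- denom[inter] - fc$mi[cbind(path[inter - 1], path[inter])]
  }
  if (any(edge_mi == 0)) {
    return(c(raw = Inf, per_mm = Inf))
  }
  raw <- -sum(log2(edge_mi / denom))
  c(raw = raw, per_mm = raw / length_mm)
}

#' Add path broadcasting strengths to a path table
#'
#' Evaluates [compute_pbs()] for every connected ordered pair (direct pairs
#' included). Pairs whose path crosses a zero-MI edge get `Inf` (infinitely
#' hidden path) with a warning; disconnected pairs get `NA`.
#'
#' @param paths Path table from [shortest_paths()] (a `pps`/`regime`
#'   column, if present, is preserved).
#' @param fc A [functional_connectome()].
#' @param sc The [structural_connectome()] the paths were computed on.
#' @param exclude_incoming See [compute_pbs()].
#' @return The table with added columns `pbs_raw` (bits) and `pbs`
#'   (bits/mm).
#' @export
add_pbs <- function(paths, fc, sc, exclude_incoming = FALSE) {
  region_ids <- attr(paths, "region_ids")
  if (!identical(region_ids, fc$region_ids)) {
    abort("path table and functional connectome use different region sets.")
  }
  check_same_regions(fc, sc, "connectomes")
  w <- strength_vector(fc, sc)
  raw <- rep(NA_real_, nrow(paths))
  per_mm <- rep(NA_real_, nrow(paths))
  conn <- which(paths$connected)
  for (k in conn) {
    v <- compute_pbs(paths$path[[k]], fc, strengths = w,
                     length_mm = paths$length_mm[k],
                     exclude_incoming = exclude_incoming)
    raw[k] <- v[["raw"]]
    per_mm[k] <- v[["per_mm"]]
  }
  n_inf <- sum(is.infinite(raw), na.rm = TRUE)
  if (n_inf > 0) {
    warn(sprintf(
      "%d path(s) cross a zero-MI edge; their PBS is infinite and will be excluded from nodal broadcasting sums.",
      n_inf
    ))
  }
  out <- paths
  out$pbs_raw <- raw
  out$pbs <- per_mm
  attr(out, "region_ids") <- region_ids
  attr(out, "boundaries") <- attr(paths, "boundaries")
  out
}

#' Path broadcasting strengths as N x N matrices
#'
#' @inheritParams add_pbs
#' @param normalized Return bits/mm (`TRUE`, default) or raw bits.
#' @return Numeric matrix, `NA` for diagonal and disconnected pairs.
#' @export
pbs_matrix <- function(paths, fc = NULL, sc = NULL, normalized = TRUE,
                       exclude_incoming = FALSE) {
  tab <- if ("pbs" %in% names(paths)) paths
         else add_pbs(paths, fc, sc, exclude_incoming)
  region_ids <- attr(paths, "region_ids")
  n <- length(region_ids)
  m <- matrix(NA_real_, n, n, dimnames = list(region_ids, region_ids))
  m[cbind(tab$source, tab$target)] <- if (normalized) tab$pbs else tab$pbs_raw
  m
}

#' Nodal broadcasting strengths per communication regime
#'
#' Aggregates normalized PBS into per-region sender and receiver
#' broadcasting strengths over the pairs carrying a given regime label:
#' `WBS_sender(k)` sums PBS over pairs with k as source,
#' `WBS_receiver(k)` over pairs with k as target, and the symmetric
#' `WBS(k)` is their average. Undefined or infinite PBS entries are
#' excluded from the sums; the number of exclusions is attached as
#' attribute `n_excluded`.
#'
#' @param paths_scored Path table with `regime` and `pbs` columns (see
#'   [classify_regimes()] and [add_pbs()]).
#' @param regime One of `"direct"`, `"relay"`, `"transducted"`.
#' @return Tibble with columns `region_index`, `region`, `wbs_sender`,
#'   `wbs_receiver`, `wbs` (all bits/mm) and `regime`; class
#'   `broadcast_strengths`.
#' @export
broadcast_strengths <- function(paths_scored,
                                regime = c("direct", "relay", "transducted")) {
  regime <- match.arg(regime)
  for (col in c("regime", "pbs")) {
    if (!col %in% names(paths_scored)) {
      abort(sprintf("`paths_scored` has no `%s` column.", col))
    }
  }
  region_ids <- attr(paths_scored, "region_ids")
  n <- length(region_ids)
  sel <- !is.na(paths_scored$regime) & paths_scored$regime == regime
  defined <- sel & is.finite(paths_scored$pbs)
  n_excluded <- sum(sel & !is.finite(paths_scored$pbs))
  sub <- paths_scored[defined, ]
  sender <- rep(0, n)
  receiver <- rep(0, n)
  if (nrow(sub)) {
    agg_s <- tapply(sub$pbs, sub$source, sum)
    agg_r <- tapply(sub$pbs, sub$target, sum)
    sender[as.integer(names(agg_s))] <- agg_s
    receiver[as.integer(names(agg_r))] <- agg_r
  }
  out <- tibble(
    region_index = seq_len(n),
    region = region_ids,
    wbs_sender = sender,
    wbs_receiver = receiver,
    wbs = (sender + receiver) / 2,
    regime = regime
  )
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("broadcast_strengths", class(out))
  out
}

#' Top broadcasting regions
#'
#' Ranks regions by symmetric nodal broadcasting strength, descending;
#' ties are resolved deterministically by region index.
#'
#' @param bs A [broadcast_strengths()] tibble.
#' @param k Number of regions to return (default 10).
#' @return The top `k` rows, with an added `rank` column.
#' @export
top_regions <- function(bs, k = 10) {
  if (k > nrow(bs)) abort("`k` exceeds the number of regions.")
  ord <- order(-bs$wbs, bs$region_index)
  out <- bs[ord[seq_len(k)], ]
  out$rank <- seq_len(k)
  out
}
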