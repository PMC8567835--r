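#' Path processing score of a single shortest path
#'
#' The path processing score (PPS) quantifies how much a signal traveling
#' from source S to target T along the structural geodesic
#' `(S, K1, ..., Km, T)` has been transformed, using the mutual-information
#' functional connectome: for every post-source node i the difference
#' `MI(S, K1) - MI(S, i)` is accumulated,
#' `PPS = sum_{i in (K1,...,Km,T)} [MI(S, K1) - MI(S, i)]`
#' (the K1 term is identically zero). Positive values indicate attenuation
#' or transformation of the signal along the path; negative values violate
#' the data-processing-inequality expectation and are evidence that the
#' path is not in use. PPS is not defined for single-edge geodesics and is
#' generally nonsymmetric in (S, T).
#'
#' The default `mode = "anchor"` keeps `MI(S, K1)` as the reference for
#' every summand. `mode = "telescoping"` is a non-default alternative
#' reading with consecutive differences, which collapses to
#' `MI(S, K1) - MI(S, T)`; the two coincide on 2-edge paths.
#'
#' @param path Integer (or region-name) node sequence of the geodesic,
#'   source first.
#' @param fc A [functional_connectome()].
#' @param mode `"anchor"` (default) or `"telescoping"`.
#' @return PPS in bits.
#' @examples
#' fx <- toy_fixture()
#' compute_pps(c(1, 2, 3, 5), fx$fc)   # A -> B -> C -> E
#' @export
compute_pps <- function(path, fc, mode = c("anchor", "telescoping")) {
  mode <- match.arg(mode)
  if (!inherits(fc, "functional_connectome")) {
    abort("`fc` must be a functional_connectome.")
  }
  if (is.character(path)) {
    path <- vapply(path, resolve_region, 1L, region_ids = fc$region_ids)
  }
  if (length(path) < 3) {
    abort("PPS is not defined for single-edge shortest paths.")
  }
  s <- path[1]
  rest <- path[-1]
  anchor <- fc$mi[s, rest[1]]
  if (mode == "anchor") {
    sum(anchor - fc$mi[s, rest])
  } else {
    anchor - fc$mi[s, path[length(path)]]
  }
}

#' Add path processing scores to a path table
#'
#' Evaluates [compute_pps()] for every ordered pair whose geodesic has at
#' least two edges; single-edge (direct) and disconnected pairs get `NA`
#' (PPS undefined).
#'
#' @param paths Output of [shortest_paths()].
#' @param fc A [functional_connectome()] on the same regions.
#' @param mode Passed to [compute_pps()].
#' @return `paths` with an added numeric column `pps` (bits).
#' @export
add_pps <- function(paths, fc, mode = c("anchor", "telescoping")) {
  mode <- match.arg(mode)
  region_ids <- attr(paths, "region_ids")
  if (!identical(region_ids, fc$region_ids)) {
    abort("path table and functional connectome use different region sets.")
  }
  pps <- rep(NA_real_, nrow(paths))
  multi <- which(paths$connected & paths$hops >= 2)
  for (k in multi) {
    pps[k] <- compute_pps(paths$path[[k]], fc, mode)
  }
  out <- paths
  out$pps <- pps
  attr(out, "region_ids") <- region_ids
  out
}

#' Path processing scores as an N x N matrix
#'
#' @inheritParams add_pps
#' @return Numeric matrix with `NA` where PPS is undefined (diagonal,
#'   direct pairs, disconnected pairs).
#' @export
pps_matrix <- function(paths, fc, mode = c("anchor", "telescoping")) {
  tab <- if ("pps" %in% names(paths)) paths else add_pps(paths, fc, mode)
  region_ids <- attr(paths, "region_ids")
  n <- length(region_ids)
  m <- matrix(NA_real_, n, n, dimnames = list(region_ids, region_ids))
  m[cbind(tab$source, tab$target)] <- tab$pps
  m
}

#' Relay-regime boundaries
#'
#' The relay communication regime is the closed PPS interval
#' `[lower, upper]`. The defaults, -0.04 and 0.07 bits, are the published
#' 5th/95th percentiles of the resting-state default-mode-network PPS
#' distribution; [estimate_boundaries()] recomputes them from data.
#'
#' @param lower,upper Boundaries in bits; `lower < upper` required.
#' @param provenance Free-form description of how the boundaries were
#'   obtained.
#' @return Object of class `regime_boundaries`.
#' @export
regime_boundaries <- function(lower = -0.04, upper = 0.07,
                              provenance = "package default") {
  if (!is.numeric(lower) || !is.numeric(upper) || !(lower < upper)) {
    abort(sprintf(
      "invalid regime boundaries: need lower < upper, got (%g, %g).",
      lower, upper
    ))
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 provenance = provenance),
            class = "regime_boundaries")
}

#' @export
print.regime_boundaries <- function(x, ...) {
  cat(sprintf("<regime_boundaries> relay = [%g, %g] bits (%s)\n",
              x$lower, x$upper, x$provenance))
  invisible(x)
}

#' Estimate relay boundaries from a within-network PPS distribution
#'
#' Takes the defined PPS values of all ordered pairs whose source and
#' target both belong to `network` (by default the default mode network, a
#' highly coherent system at rest whose paths are expected to operate in
#' relay) and returns the requested percentiles as the relay interval. To
#' pool across subjects, row-bind their scored path tables before calling.
#'
#' @param paths_pps A path table with a `pps` column (see [add_pps()]), or
#'   several subjects' tables row-bound together.
#' @param parcellation Parcellation tibble (region, network, hemisphere).
#' @param network Network label defining the reference distribution
#'   (default `"Default"`).
#' @param percentiles Length-2 percentile pair, default `c(5, 95)`.
#' @return A [regime_boundaries()] object with provenance recorded.
#' @export
estimate_boundaries <- function(paths_pps, parcellation,
                                network = "Default",
                                percentiles = c(5, 95)) {
  parcellation <- validate_parcellation(parcellation)
  if (!network %in% parcellation$network) {
    abort(sprintf("network %s not present in the parcellation.",
                  sQuote(network)))
  }
  if (length(percentiles) != 2 || percentiles[1] >= percentiles[2]) {
    abort("`percentiles` must be an increasing pair in [0, 100].")
  }
  if (!"pps" %in% names(paths_pps)) {
    abort("`paths_pps` has no `pps` column; run add_pps() first.")
  }
  members <- parcellation$region[parcellation$network == network]
  vals <- paths_pps$pps[
    paths_pps$source_region %in% members &
      paths_pps$target_region %in% members
  ]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 20) {
    abort(sprintf(
      "only %d defined PPS values within network %s; need >= 20 for a stable percentile.",
      length(vals), sQuote(network)
    ))
  }
  q <- unname(quantile(vals, percentiles / 100))
  if (!(q[1] < q[2])) {
    abort(sprintf(
      "degenerate PPS distribution within %s: percentiles collapse to (%g, %g).",
      sQuote(network), q[1], q[2]
    ))
  }
  regime_boundaries(q[1], q[2], provenance = sprintf(
    "percentiles [%g, %g] of %d within-%s PPS values",
    percentiles[1], percentiles[2], length(vals), network
  ))
}

regime_levels <- function() {
  c("direct", "absent", "relay", "transducted", "disconnected")
}

#' Classify every source-target pair into a communication regime
#'
#' Pairs whose geodesic is a single structural edge are `direct` (PPS is
#' not defined there). Multi-edge pairs are classified by PPS against the
#' relay boundaries: `absent` below `lower` (evidence the path is unused),
#' `relay` inside the closed interval `[lower, upper]` (signal passed
#' nearly intact), `transducted` above `upper` (signal transformed).
#' Structurally disconnected pairs are labelled `disconnected`.
#'
#' @param paths_pps Path table with `pps` column (see [add_pps()]).
#' @param boundaries A [regime_boundaries()] object.
#' @return The table with an added factor column `regime` with levels
#'   direct, absent, relay, transducted, disconnected.
#' @export
classify_regimes <- function(paths_pps, boundaries = regime_boundaries()) {
  if (!inherits(boundaries, "regime_boundaries")) {
    abort("`boundaries` must be a regime_boundaries object.")
  }
  if (!"pps" %in% names(paths_pps)) {
    abort("`paths_pps` has no `pps` column; run add_pps() first.")
  }
  lab <- rep(NA_character_, nrow(paths_pps))
  lab[!paths_pps$connected] <- "disconnected"
  lab[paths_pps$connected & paths_pps$hops == 1] <- "direct"
  multi <- paths_pps$connected & paths_pps$hops >= 2
  p <- paths_pps$pps
  lab[multi & p < boundaries$lower] <- "absent"
  lab[multi & p >= boundaries$lower & p <= boundaries$upper] <- "relay"
  lab[multi & p > boundaries$upper] <- "transducted"
  out <- paths_pps
  out$regime <- factor(lab, levels = regime_levels())
  attr(out, "region_ids") <- attr(paths_pps, "region_ids")
  attr(out, "boundaries") <- boundaries
  out
}
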