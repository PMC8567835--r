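#' Tidy a communication analysis into a per-pair tibble
#'
#' One row per ordered source-target pair with the scored quantities:
#' geodesic hop count and length, PPS (bits), regime, raw and normalized
#' PBS. The node sequence is flattened to a `"A->B->C"` string.
#'
#' @param x A `comm_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.comm_analysis <- function(x, ...) {
  p <- x$pairs
  ids <- attr(p, "region_ids")
  tibble(
    source = p$source_region,
    target = p$target_region,
    connected = p$connected,
    hops = p$hops,
    length_mm = p$length_mm,
    path = map(p$path, function(q) {
      if (is.null(q)) NA_character_ else paste(ids[q], collapse = "->")
    }) |> unlist(),
    pps = p$pps,
    regime = p$regime,
    pbs_raw = p$pbs_raw,
    pbs = p$pbs
  )
}

#' One-row summary of a communication analysis
#'
#' @param x A `comm_analysis` object.
#' @param ... Unused.
#' @return One-row tibble: region/pair counts, per-regime pair counts,
#'   relay boundaries, and mean normalized PBS per regime.
#' @export
glance.comm_analysis <- function(x, ...) {
  p <- x$pairs
  cnt <- function(r) sum(!is.na(p$regime) & p$regime == r)
  mean_pbs <- function(r) {
    v <- p$pbs[!is.na(p$regime) & p$regime == r & is.finite(p$pbs)]
    if (length(v)) mean(v) else NA_real_
  }
  tibble(
    n_regions = length(attr(p, "region_ids")),
    n_pairs = nrow(p),
    n_direct = cnt("direct"),
    n_absent = cnt("absent"),
    n_relay = cnt("relay"),
    n_transducted = cnt("transducted"),
    n_disconnected = cnt("disconnected"),
    lower = x$boundaries$lower,
    upper = x$boundaries$upper,
    mean_pbs_direct = mean_pbs("direct"),
    mean_pbs_relay = mean_pbs("relay"),
    mean_pbs_transducted = mean_pbs("transducted")
  )
}
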