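#' Stratify communication regimes by functional network
#'
#' Counts, for each regime, the ordered (source network, target network)
#' pairs among its paths, and converts counts to percentages of that
#' regime's total. With `pairs = "unordered"`, (A, B) and (B, A) are
#' merged into the cell with the alphabetically first network as row.
#'
#' @param paths_scored Path table with a `regime` column (see
#'   [classify_regimes()]).
#' @param parcellation Parcellation tibble (region, network, hemisphere)
#'   covering all regions of the path table.
#' @param pairs `"ordered"` (default) or `"unordered"` network pairs.
#' @return Long tibble with columns `regime`, `source_network`,
#'   `target_network`, `n`, `pct`; class `network_regime_summary`.
#'   Within each regime the `pct` column sums to 100 over all cells.
#' @export
regime_by_network <- function(paths_scored, parcellation,
                              pairs = c("ordered", "unordered")) {
  pairs <- match.arg(pairs)
  parcellation <- validate_parcellation(parcellation)
  if (!"regime" %in% names(paths_scored)) {
    abort("`paths_scored` has no `regime` column; run classify_regimes().")
  }
  region_ids <- attr(paths_scored, "region_ids")
  missing <- setdiff(region_ids, parcellation$region)
  if (length(missing)) {
    abort(sprintf("parcellation lacks %d region(s), e.g. %s.",
                  length(missing), missing[1]))
  }
  net <- parcellation$network[match(region_ids, parcellation$region)]
  tab <- paths_scored[!is.na(paths_scored$regime) &
                        paths_scored$regime %in%
                          c("direct", "absent", "relay", "transducted"), ]
  src_net <- net[tab$source]
  tgt_net <- net[tab$target]
  if (pairs == "unordered") {
    a <- pmin(src_net, tgt_net)
    b <- pmax(src_net, tgt_net)
    src_net <- a
    tgt_net <- b
  }
  counts <- tibble(regime = as.character(tab$regime),
                   source_network = src_net,
                   target_network = tgt_net) |>
    count(.data$regime, .data$source_network, .data$target_network,
          name = "n") |>
    group_by(.data$regime) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  class(counts) <- c("network_regime_summary", class(counts))
  attr(counts, "pairs") <- pairs
  counts
}

#' Sender-receiver asymmetry of nodal broadcasting
#'
#' Per-region difference between sender and receiver broadcasting
#' strengths, `delta = WBS_sender - WBS_receiver`, with distribution
#' summaries. A positive delta marks a region that broadcasts more as a
#' source than it receives as a target. No hypothesis testing is
#' performed; the per-node vector is suitable input for any external rank
#' test.
#'
#' @param bs A [broadcast_strengths()] tibble.
#' @return List with `per_node` (tibble: region_index, region, wbs_sender,
#'   wbs_receiver, delta) and `stats` (one-row tibble: regime, median,
#'   iqr, mean, n_positive, n_negative).
#' @export
asymmetry_summary <- function(bs) {
  for (col in c("wbs_sender", "wbs_receiver")) {
    if (!col %in% names(bs)) abort(sprintf("`bs` lacks column %s.", col))
  }
  per_node <- tibble(
    region_index = bs$region_index,
    region = bs$region,
    wbs_sender = bs$wbs_sender,
    wbs_receiver = bs$wbs_receiver,
    delta = bs$wbs_sender - bs$wbs_receiver
  )
  stats <- tibble(
    regime = if ("regime" %in% names(bs)) bs$regime[1] else NA_character_,
    median = stats::median(per_node$delta),
    iqr = stats::IQR(per_node$delta),
    mean = mean(per_node$delta),
    n_positive = sum(per_node$delta > 0),
    n_negative = sum(per_node$delta < 0)
  )
  list(per_node = per_node, stats = stats)
}
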