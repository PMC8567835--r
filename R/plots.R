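#' Plot regime percentages per functional-network pair
#'
#' Tile heatmap of the percentage of each regime's paths falling in every
#' (source network, target network) cell, one facet per regime.
#'
#' @param object A `network_regime_summary` (see [regime_by_network()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.network_regime_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$target_network, y = .data$source_network,
                     fill = .data$pct)) +
    geom_tile() +
    facet_wrap(~regime) +
    scale_fill_gradient(low = "white", high = "firebrick",
                        name = "% of regime's paths") +
    labs(x = "target network", y = "source network") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot sender/receiver broadcasting strengths of the top regions
#'
#' Dodged bars of WBS_sender and WBS_receiver (bits/mm) for the `k`
#' regions with the highest symmetric WBS, mirroring the standard
#' top-regions broadcasting ranking.
#'
#' @param object A `broadcast_strengths` tibble.
#' @param k Number of regions to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.broadcast_strengths <- function(object, k = 10, ...) {
  top <- top_regions(object, min(k, nrow(object)))
  long <- tidyr::pivot_longer(
    top[c("region", "wbs_sender", "wbs_receiver")],
    cols = c("wbs_sender", "wbs_receiver"),
    names_to = "role", values_to = "wbs"
  )
  long$region <- factor(long$region, levels = rev(top$region))
  ggplot(long, aes(x = .data$wbs, y = .data$region, fill = .data$role)) +
    geom_col(position = position_dodge()) +
    labs(x = "nodal broadcasting strength (bits/mm)", y = NULL,
         fill = NULL,
         title = sprintf("Top regions, %s regime", object$regime[1])) +
    theme_minimal()
}

#' @rdname autoplot.network_regime_summary
#' @param summary_obj A `network_regime_summary`.
#' @export
plot_regime_fractions <- function(summary_obj) {
  autoplot.network_regime_summary(summary_obj)
}

#' @rdname autoplot.broadcast_strengths
#' @param bs A `broadcast_strengths` tibble.
#' @export
plot_broadcast_strengths <- function(bs, k = 10) {
  autoplot.broadcast_strengths(bs, k = k)
}

#' Plot the distribution of path processing scores with regime boundaries
#'
#' @param object A `comm_analysis` object.
#' @param ... Unused.
#' @return A ggplot object (PPS histogram with the relay interval marked).
#' @export
autoplot.comm_analysis <- function(object, ...) {
  d <- object$pairs
  d <- d[!is.na(d$pps), ]
  ggplot(d, aes(x = .data$pps)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey60") +
    ggplot2::geom_vline(xintercept = c(object$boundaries$lower,
                                       object$boundaries$upper),
                        linetype = "dashed", colour = "firebrick") +
    labs(x = "path processing score (bits)", y = "ordered pairs",
         title = "PPS distribution with relay boundaries") +
    theme_minimal()
}
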