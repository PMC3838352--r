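#' Plot a node-score distribution
#'
#' Histogram of normalized node scores, seeds overplotted as a rug, so the
#' separation of the seed neighbourhood from the network background is
#' visible at a glance.
#'
#' @param object A `node_scores` tibble.
#' @param bins Histogram bins (default 40).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.node_scores <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_rug(data = dplyr::filter(object, .data$is_seed),
                      colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = sprintf("%s score (normalized)", attr(object, "method")),
                  y = "nodes",
                  title = "Node relevance scores (seeds marked in red)") +
    ggplot2::theme_minimal()
}

#' Plot a cutoff scan
#'
#' Edge and node counts against the edge-score cutoff; the elbow of this
#' curve is the usual basis for choosing a common sub-network cutoff.
#'
#' @param object A `threshold_curve` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.threshold_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("n_edges", "n_nodes"),
                              names_to = "what", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$count,
                                     colour = .data$what)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_colour_manual(values = c(n_edges = "steelblue",
                                            n_nodes = "darkorange"),
                                 labels = c(n_edges = "edges", n_nodes = "nodes"),
                                 name = NULL) +
    ggplot2::labs(x = "edge-score cutoff", y = "count retained",
                  title = "Sub-network size versus score cutoff") +
    ggplot2::theme_minimal()
}

#' Plot an organism tally
#'
#' @param object An `organism_tally` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.organism_tally <- function(object, ...) {
  kingdoms <- dplyr::filter(object, !.data$group %in%
                              c("Total", "Microbial (Viruses+Bacteria)"))
  ggplot2::ggplot(kingdoms, ggplot2::aes(x = .data$group, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "template chains",
                  title = "Source-organism composition of template chains") +
    ggplot2::theme_minimal()
}
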