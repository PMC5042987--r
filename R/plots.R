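#' Plot a temporal relatedness graph
#'
#' Draws topics as points arranged in epoch rows (time flowing downward),
#' sized by within-epoch popularity, with the graph's retained
#' connections as segments. Finite-weight edges are shaded by weight
#' (darker = more related).
#'
#' @param object A `tf_temporal_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_temporal_graph <- function(object, ...) {
  nodes <- object$nodes |>
    dplyr::group_by(.data$epoch) |>
    dplyr::mutate(x = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, from = "node", x0 = "x", e0 = "epoch"),
                     by = "from") |>
    dplyr::left_join(dplyr::select(nodes, to = "node", x1 = "x", e1 = "epoch"),
                     by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$e0, xend = .data$x1, yend = .data$e1,
                   alpha = -.data$weight),
      colour = "grey30", show.legend = FALSE) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$epoch, size = .data$popularity,
                   colour = factor(.data$epoch))) +
    ggplot2::scale_y_reverse(breaks = unique(nodes$epoch)) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(
      title = sprintf("Temporal topic graph (%s%s)", object$metric,
                      if (object$pruned) sprintf(", zeta = %.2f", object$zeta) else ", full"),
      x = NULL, y = "epoch", colour = "epoch", size = "popularity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Plot an epoch's topics as top-term profiles
#'
#' @param object A `tf_topics` topic set.
#' @param n_terms Terms shown per topic.
#' @param ... Unused.
#' @return A ggplot object (one facet per topic).
#' @export
autoplot.tf_topics <- function(object, n_terms = 10L, ...) {
  df <- tidy(object, n_terms = n_terms)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$prob,
    y = stats::reorder(interaction(.data$topic, .data$term, sep = ": "), .data$prob))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$topic), scales = "free_y") +
    ggplot2::scale_y_discrete(labels = function(l) sub("^[^:]*: ", "", l)) +
    ggplot2::labs(title = sprintf("Epoch %d topics", object$epoch),
                  x = "term probability", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cross-metric shared-edge fractions
#'
#' @param overlap Tibble from [shared_edge_fraction()] (with `epoch` and
#'   `fraction` columns).
#' @return A ggplot object.
#' @export
plot_shared_edges <- function(overlap) {
  ggplot2::ggplot(overlap, ggplot2::aes(x = .data$epoch, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "epoch pair (earlier epoch)",
                  y = "fraction of connections shared") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
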