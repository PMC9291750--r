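#' Plot net-displacement series
#'
#' Distance from first detection against age, one line per calf, with the
#' spatial threshold drawn when supplied.
#'
#' @param object A [displacement_series()] tibble.
#' @param threshold Optional threshold radius (km) to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.displacement_series <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age_months,
                                            y = .data$distance_km,
                                            group = .data$id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "Age (months)", y = "Net displacement (km)")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Plot sex-specific predicted dispersal-type probabilities
#'
#' @param object A [predicted_probabilities()] tibble.
#' @param ... Unused.
#' @return A ggplot of probability curves against the focal covariate,
#'   one panel per grouping level.
#' @export
autoplot.predicted_probabilities <- function(object, ...) {
  focal <- attr(object, "focal")
  by <- attr(object, "by")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[focal]],
                                            y = .data$probability,
                                            colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = focal, y = "Predicted probability",
                  colour = "Dispersal type")
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(by)
  p
}

#' Plot the adult-female association network coloured by community
#'
#' Nodes placed by force-directed layout (deterministic given `seed`),
#' edges filtered below `min_sri` for legibility.
#'
#' @param assoc Association matrix from [simple_ratio_index()].
#' @param partition A [detect_communities()] partition.
#' @param min_sri Minimum edge weight drawn.
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_association_network <- function(assoc, partition, min_sri = 0.05,
                                     seed = 1L) {
  mem <- partition_membership(partition)
  set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(assoc, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(
    id = rownames(assoc), x = lay[, 1], y = lay[, 2],
    community = factor(mem$community[match(rownames(assoc), mem$id)])
  )
  ew <- igraph::as_data_frame(g, what = "edges") |>
    filter(.data$weight >= min_sri) |>
    mutate(
      x = nodes$x[match(.data$from, nodes$id)],
      y = nodes$y[match(.data$from, nodes$id)],
      xend = nodes$x[match(.data$to, nodes$id)],
      yend = nodes$y[match(.data$to, nodes$id)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ew,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       alpha = .data$weight),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$community), size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "Community", alpha = "SRI")
}
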