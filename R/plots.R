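#' Plot an EET graph
#'
#' Projects chromophore anchors onto a chosen coordinate plane and draws the
#' sub-cutoff edges, colouring nodes by group label when present.
#'
#' @param object An `eet_graph`.
#' @param plane Two coordinate names to plot, a subset of `c("x","y","z")`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.eet_graph <- function(object, plane = c("x", "y"), ...) {
  stopifnot(length(plane) == 2L, all(plane %in% c("x", "y", "z")))
  nodes <- object$nodes
  nodes$px <- nodes[[plane[1L]]]
  nodes$py <- nodes[[plane[2L]]]
  edges <- object$edges
  ia <- match(edges$site_a, nodes$site_id)
  ib <- match(edges$site_b, nodes$site_id)
  seg <- tibble(
    x = nodes$px[ia], y = nodes$py[ia],
    xend = nodes$px[ib], yend = nodes$py[ib],
    distance = edges$distance)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = -.data$distance),
      colour = "grey60", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.1, 0.6)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$px, y = .data$py,
                   colour = .data$group_label), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(plane[1L], " (A)"), y = paste0(plane[2L], " (A)"),
                  colour = "group",
                  title = sprintf("chromophore network (cutoff %.0f A)",
                                  object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Histogram of sub-cutoff inter-bilin distances
#' @param graph An `eet_graph` (or an edge tibble with a `distance` column).
#' @param binwidth Histogram bin width in Angstrom.
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(graph, binwidth = 2) {
  edges <- if (inherits(graph, "eet_graph")) graph$edges else as_tibble(graph)
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "inter-bilin distance (A)", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot a packing comparison
#'
#' Minimal inter-hexamer bilin distance per junction, faceted by model, with
#' bars coloured by the single-pathway / network classification.
#'
#' @param object A `packing_report` from [compare_packings()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.packing_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$junction, y = .data$min_distance,
                               fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$model), scales = "free_x") +
    ggplot2::labs(x = "junction", y = "minimal bilin distance (A)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a census result
#' @param object A `census_result`.
#' @param ... Ignored.
#' @return A ggplot object showing chromophore counts per compartment.
#' @export
autoplot.census_result <- function(object, ...) {
  ggplot2::ggplot(object$chromophores_by_compartment,
                  ggplot2::aes(x = .data$compartment, y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "chromophores") +
    ggplot2::theme_minimal()
}
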