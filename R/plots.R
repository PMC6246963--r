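#' Plot a consensus convergence curve
#'
#' One line per food: the mean consensus estimate as the crowd grows, with a
#' ribbon of +/- one SD across draws, on a log-scaled crowd-size axis, and
#' dashed lines at each food's true calorie value.
#'
#' @param object A `crowd_convergence` tibble from [convergence_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crowd_convergence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_estimate - .data$sd_estimate,
                   ymax = .data$mean_estimate + .data$sd_estimate),
      fill = "grey80"
    ) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth_kcal),
                        linetype = "dashed", colour = "#1f78b4") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~food_id, scales = "free_y") +
    ggplot2::labs(x = "crowd size k (log scale)",
                  y = "consensus estimate (kcal)",
                  title = "Crowd consensus forms rapidly") +
    ggplot2::theme_minimal()
}

#' Plot the density-bias curve
#'
#' Mean percent error per food against energy density (log-scaled x):
#' energy-sparse foods underestimated, energy-dense foods overestimated
#' shows up as an increasing trend crossing zero.
#'
#' @param object A `density_bias_curve` tibble from [density_bias_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_bias_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$energy_density, y = .data$mean_eta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$food_id),
                       vjust = -0.6, size = 2.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "energy density (kcal/g, log scale)",
                  y = "mean percent error",
                  title = "Estimation bias vs energy density") +
    ggplot2::theme_minimal()
}

#' Plot the food error-correlation graph
#'
#' A simple force-directed rendering of the thresholded error-correlation
#' network: edge width scales with correlation, node colour with cluster.
#'
#' @param graph Graph from [build_food_graph()].
#' @param clusters Optional tibble from [cluster_foods()].
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_food_graph <- function(graph, clusters = NULL, seed = 1L) {
  set.seed(seed)
  xy <- igraph::layout_with_fr(graph)
  nodes <- tibble::tibble(
    food_id = igraph::V(graph)$name, x = xy[, 1], y = xy[, 2]
  )
  if (!is.null(clusters)) {
    nodes <- dplyr::left_join(nodes, clusters, by = "food_id") %>%
      dplyr::mutate(cluster = factor(.data$cluster))
  } else {
    nodes$cluster <- factor(1)
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  edges <- tibble::tibble(
    x = nodes$x[match(el$from, nodes$food_id)],
    y = nodes$y[match(el$from, nodes$food_id)],
    xend = nodes$x[match(el$to, nodes$food_id)],
    yend = nodes$y[match(el$to, nodes$food_id)],
    correlation = el$correlation
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$correlation),
      colour = "grey70"
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$cluster), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$food_id),
                       vjust = -1, size = 2.7) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::labs(title = "Food error-correlation network",
                  colour = "cluster") +
    ggplot2::theme_void()
}
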