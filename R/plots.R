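#' @importFrom ggplot2 ggplot aes autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a trait network with module colouring
#'
#' Draws the network on a deterministic circular layout: nodes coloured by
#' detected module, edges drawn black within modules and red between modules —
#' the conventional rendering of PTN figures.
#'
#' @param net A `ptn` object.
#' @param metrics Optional `ptn_metrics` for the same network (computed with
#'   defaults if omitted).
#' @return A ggplot object. The plotted numbers are available from
#'   `tidy(net)` and `tidy(metrics)`.
#' @export
plot_ptn <- function(net, metrics = NULL) {
  if (is.null(metrics)) metrics <- network_metrics(net)
  p <- length(net$traits)
  theta <- 2 * pi * (seq_len(p) - 1) / p
  nodes <- tibble(trait = net$traits, x = cos(theta), y = sin(theta),
                  module = factor(metrics$membership[net$traits]),
                  degree = as.integer(metrics$degree[net$traits]))
  el <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  edges <- tibble(
    x = nodes$x[el[, 1]], y = nodes$y[el[, 1]],
    xend = nodes$x[el[, 2]], yend = nodes$y[el[, 2]],
    within = metrics$membership[el[, 1]] == metrics$membership[el[, 2]]
  )
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
          colour = .data$within),
      linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red")) +
    ggplot2::geom_point(aes(fill = .data$module, size = .data$degree),
                        shape = 21) +
    ggplot2::geom_text(aes(label = .data$trait), vjust = -1.3, size = 3) +
    ggplot2::scale_size_continuous(range = c(2, 7)) +
    ggplot2::coord_equal(clip = "off") +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = sprintf("Trait network: density %.2f, modularity %.2f",
                      metrics$edge_density, metrics$modularity))
}

#' Degree bars with bootstrap error bars (and Duncan letters)
#'
#' @param boot A `ptn_boot` object.
#' @param duncan Optional `ptn_duncan` over the same traits; its letters are
#'   printed above the bars.
#' @return A ggplot object.
#' @export
plot_degree <- function(boot, duncan = NULL) {
  deg <- boot$summary |>
    dplyr::filter(.data$parameter == "degree") |>
    dplyr::arrange(dplyr::desc(.data$mean), .data$trait)
  deg$trait <- factor(deg$trait, levels = deg$trait)
  gg <- ggplot(deg, aes(x = .data$trait, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(aes(ymin = .data$mean - .data$se,
                               ymax = .data$mean + .data$se), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Degree (bootstrap mean ± SE)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(duncan)) {
    lab <- tidy(duncan)
    deg <- dplyr::left_join(deg, dplyr::select(lab, "item", "letters"),
                            by = c(trait = "item"))
    gg <- gg + ggplot2::geom_text(
      data = deg, aes(label = .data$letters, y = .data$mean + .data$se),
      vjust = -0.5, size = 3)
  }
  gg
}

#' @rdname plot_degree
#' @param object A `ptn_boot` object.
#' @param ... Unused.
#' @method autoplot ptn_boot
#' @export
autoplot.ptn_boot <- function(object, ...) plot_degree(object)

#' Category importance bars
#'
#' @param importance A tibble from [trait_importance()].
#' @param relative Plot relative (default) or absolute importance.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, relative = FALSE) {
  yvar <- if (relative) "relative_importance" else "absolute_importance"
  ggplot(importance, aes(x = stats::reorder(.data$category, -.data[[yvar]]),
                         y = .data[[yvar]], fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL,
                  y = if (relative) "Relative importance" else
                    "Absolute importance (mean degree)") +
    ggplot2::theme_minimal()
}

#' @rdname rarefy_ptn
#' @param object A `ptn_rarefaction` object.
#' @method autoplot ptn_rarefaction
#' @export
autoplot.ptn_rarefaction <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$species_count, y = .data$mean)) +
    ggplot2::geom_ribbon(aes(ymin = .data$mean - .data$se,
                             ymax = .data$mean + .data$se), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Number of species", y = "Mean ± SE") +
    ggplot2::theme_minimal()
}
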