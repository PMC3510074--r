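#' Heat-map of a landscape grid
#'
#' Renders the raster in the field's usual temperature palette: red for low
#' ground (frequently used space) through to blue for high ground (avoided
#' space).
#'
#' @param object A [landscape_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.landscape_grid <- function(object, ...) {
  df <- tidy.landscape_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#b2182b", "#ef8a62", "#fddbc7", "#d1e5f0", "#67a9cf",
                  "#2166ac"),
      na.value = "grey85", name = "height"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.perceptual_landscape <- function(object, ...) {
  autoplot.landscape_grid(object$u) +
    ggplot2::labs(title = "Perceptual landscape (u = u_d + u_w)")
}

#' Observed-vs-simulated metric comparison plot
#'
#' One panel per metric: the bootstrap interval of the observed mean
#' (horizontal bar), the observed mean (black point) and the simulated
#' mean (red point).
#'
#' @param object A `metric_comparison` from [compare_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(y = .data$metric)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_low, xend = .data$ci_high,
                                       yend = .data$metric),
                          linewidth = 2, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(x = .data$obs_mean), size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$syn_mean), colour = "red",
                        size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free", ncol = 1) +
    ggplot2::labs(x = "metric value",
                  y = NULL,
                  subtitle = "black: observed mean and its bootstrap interval; red: simulated mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   strip.text = ggplot2::element_text(hjust = 0))
}

#' Distributions of a metric set
#'
#' @param object A `metric_set` from [compute_metrics()].
#' @param ... Unused.
#' @return A ggplot object (free-scale histogram facets).
#' @export
autoplot.metric_set <- function(object, ...) {
  ggplot2::ggplot(object$distributions,
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}
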