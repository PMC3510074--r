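#' Tidy a landscape grid into cell-centre records
#'
#' @param x A [landscape_grid()].
#' @param ... Unused.
#' @return Tibble with `x`, `y` (cell centres, metres) and `height`;
#'   masked cells carry `NA`.
#' @export
tidy.landscape_grid <- function(x, ...) {
  ax <- grid_axes(x)
  tibble(
    x = rep(ax$x, each = length(ax$y)),
    y = rep(ax$y, times = length(ax$x)),
    height = as.vector(x$values)
  )
}

#' @export
glance.landscape_grid <- function(x, ...) {
  tibble(nx = ncol(x$values), ny = nrow(x$values), cellsize = x$cellsize,
         x0 = x$x0, y0 = x$y0,
         min = min(x$values, na.rm = TRUE), max = max(x$values, na.rm = TRUE),
         n_masked = sum(is.na(x$values)))
}

#' Tidy a rate model into long form
#'
#' @param x A [rate_model()].
#' @param ... Unused.
#' @return Tibble `from`, `to`, `leave_rate`, `transit_rate` (1/s), one
#'   row per ordered box pair.
#' @export
tidy.rate_model <- function(x, ...) {
  n <- length(x$boxes)
  tibble(
    from = rep(x$boxes, times = n),
    to = rep(x$boxes, each = n),
    leave_rate = as.vector(x$leave),
    transit_rate = as.vector(x$transit)
  )
}

#' @export
glance.rate_model <- function(x, ...) {
  tibble(n_boxes = length(x$boxes),
         n_active_transits = sum(x$leave > 0),
         mean_stay = mean(1 / rowSums(x$leave)),
         normalised = x$normalised)
}

#' @export
tidy.metric_set <- function(x, ...) x$distributions

#' @export
glance.metric_set <- function(x, ...) {
  tidyr::pivot_wider(x$scalars, names_from = "metric", values_from = "value")
}

#' @export
glance.perceptual_landscape <- function(x, ...) {
  tibble(n_bridges = nrow(x$bridges), vbar = x$vbar, D_bar = x$D_bar,
         D_r = x$D_r, relief = diff(range(x$u$values, na.rm = TRUE)))
}
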