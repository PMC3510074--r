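#' Per-bridge diffusion coefficient
#'
#' A transit of straight-line length `L` completed in time `T` is modelled
#' as drift at speed `L/T` plus isotropic diffusion. Requiring the mean
#' square displacement at arrival, `v_drift^2 T^2 + 4 D T`, to equal the
#' distance an animal travelling at the effective speed `vbar` would cover,
#' `(vbar T)^2`, gives
#' \deqn{D = (\bar v^2 - (L/T)^2)\, T / 4.}
#' The straightest bridge (where `L/T = vbar`) has `D = 0`; slower bridges
#' meander more and receive a larger `D`.
#'
#' @param L Straight-line bridge length, metres (vectorised).
#' @param T_ Transit duration, seconds.
#' @param vbar Effective speed from [calibrate_vbar()], m/s.
#' @return Diffusion coefficient(s), m^2/s.
#' @export
bridge_diffusion <- function(L, T_, vbar) {
  assert_scalar_number(vbar, "vbar", positive = TRUE)
  if (any(T_ <= 0)) abort("Transit duration must be > 0.")
  if (any(L < 0)) abort("Bridge length must be >= 0.")
  v_drift <- L / T_
  if (any(v_drift > vbar * (1 + 1e-12))) {
    abort("Found a bridge with drift speed above `vbar`: the effective speed must be calibrated on the straightest bridge (see calibrate_vbar()).")
  }
  pmax((vbar^2 - v_drift^2) * T_ / 4, 0)
}

#' Build Brownian bridges from bridge statistics
#'
#' Attaches to every bridge its endpoint coordinates, its diffusion
#' coefficient and the endpoint position variances. Sampling sites are not
#' points: an animal detected "at" a site is somewhere inside it, so each
#' bridge endpoint carries a finite positional variance (default
#' `(radius/2)^2` per axis), which also keeps the bridge density finite at
#' its ends.
#'
#' @param bridges Tibble from [bridge_summary()].
#' @param layout Site layout.
#' @param vbar Effective speed, m/s (see [calibrate_vbar()]).
#' @param endpoint_sd Optional endpoint standard deviation in metres; the
#'   default uses half the site radius of each endpoint's site.
#' @return A `bridge_set` tibble: the input plus `x1`, `y1`, `x2`, `y2`,
#'   `diffusion` (m^2/s), `sigma_s2`, `sigma_e2` (m^2).
#' @export
build_bridges <- function(bridges, layout, vbar, endpoint_sd = NULL) {
  assert_columns(bridges, c("site_a", "site_b", "n_cross", "distance",
                            "median_duration"))
  validate_layout(layout)
  ia <- match(bridges$site_a, layout$site_id)
  ib <- match(bridges$site_b, layout$site_id)
  if (anyNA(ia) || anyNA(ib)) abort("Bridge sites missing from layout.")
  out <- bridges
  out$x1 <- layout$x[ia]; out$y1 <- layout$y[ia]
  out$x2 <- layout$x[ib]; out$y2 <- layout$y[ib]
  out$diffusion <- bridge_diffusion(out$distance, out$median_duration, vbar)
  if (is.null(endpoint_sd)) {
    out$sigma_s2 <- (layout$radius[ia] / 2)^2
    out$sigma_e2 <- (layout$radius[ib] / 2)^2
  } else {
    assert_scalar_number(endpoint_sd, "endpoint_sd", positive = TRUE)
    out$sigma_s2 <- endpoint_sd^2
    out$sigma_e2 <- endpoint_sd^2
  }
  out
}

bridge_fields <- function(bridge) {
  # Accepts a one-row tibble / named list describing one bridge.
  need <- c("median_duration", "diffusion", "sigma_s2", "sigma_e2",
            "x1", "y1", "x2", "y2")
  miss <- setdiff(need, names(bridge))
  if (length(miss) > 0) {
    abort(sprintf("Bridge is missing field(s): %s", paste(miss, collapse = ", ")))
  }
  lapply(bridge[need], function(v) as.numeric(v)[1])
}

#' Time-dependent bridge variance
#'
#' Per-axis positional variance of a Brownian bridge with diffusion `D`,
#' duration `T` and endpoint variances `sigma_s2`, `sigma_e2`:
#' \deqn{\sigma^2(t) = 2Dt(1 - t/T) + (1 - t/T)^2 \sigma_s^2 + (t/T)^2 \sigma_e^2.}
#' It equals the endpoint variances at `t = 0` and `t = T` and, for equal
#' endpoints, peaks at half the transit time.
#'
#' @param t Time(s) since the start of the transit, seconds; must lie in
#'   `[0, T]`.
#' @param bridge One row of a `bridge_set` (or any list with fields
#'   `median_duration`, `diffusion`, `sigma_s2`, `sigma_e2`, `x1`, `y1`,
#'   `x2`, `y2`).
#' @return Variance(s), m^2.
#' @export
bridge_variance <- function(t, bridge) {
  b <- bridge_fields(bridge)
  T_ <- b$median_duration
  if (any(t < 0 | t > T_)) abort("`t` must lie within [0, T].")
  s <- t / T_
  2 * b$diffusion * t * (1 - s) + (1 - s)^2 * b$sigma_s2 + s^2 * b$sigma_e2
}

#' Time-dependent bridge position density
#'
#' Probability density of the bridge particle's position at time `t`: an
#' isotropic bivariate Gaussian centred on the point a constant drift would
#' have reached, `r1 + (t/T)(r2 - r1)`, with per-axis variance
#' [bridge_variance()].
#'
#' @param x,y Evaluation coordinates, metres (vectorised together).
#' @inheritParams bridge_variance
#' @return Density values, 1/m^2.
#' @export
bridge_pdf <- function(x, y, t, bridge) {
  b <- bridge_fields(bridge)
  T_ <- b$median_duration
  if (length(t) != 1) abort("`t` must be a single time.")
  if (t < 0 || t > T_) abort("`t` must lie within [0, T].")
  s2 <- bridge_variance(t, bridge)
  if (s2 <= 0) abort("Bridge variance is zero at this time; endpoint variances must be > 0.")
  mx <- b$x1 + (t / T_) * (b$x2 - b$x1)
  my <- b$y1 + (t / T_) * (b$y2 - b$y1)
  exp(-((x - mx)^2 + (y - my)^2) / (2 * s2)) / (2 * pi * s2)
}

#' Time-integrated bridge occupancy density
#'
#' The static footprint of one bridge: the time average
#' \eqn{(1/T)\int_0^T p(x, y, t)\,dt} of the bridge position density,
#' computed by adaptive quadrature. Like the time-dependent density it
#' integrates to 1 over the plane.
#'
#' @inheritParams bridge_pdf
#' @param abs_tol Absolute quadrature tolerance, 1/m^2.
#' @return Occupancy density values, 1/m^2.
#' @export
bridge_occupancy <- function(x, y, bridge, abs_tol = 1e-8) {
  b <- bridge_fields(bridge)
  T_ <- b$median_duration
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  out <- numeric(n)
  for (k in seq_len(n)) {
    q <- tryCatch(
      stats::integrate(function(tt) {
        vapply(tt, function(t1) bridge_pdf(x[k], y[k], t1, bridge), numeric(1))
      }, lower = 0, upper = T_, abs.tol = abs_tol * T_, rel.tol = 1e-8),
      error = function(e) abort(sprintf("Bridge occupancy quadrature failed at (%g, %g): %s",
                                        x[k], y[k], conditionMessage(e)))
    )
    if (q$abs.error > 10 * abs_tol * T_) {
      abort(sprintf("Quadrature tolerance not reached at (%g, %g): achieved %.3g.",
                    x[k], y[k], q$abs.error / T_))
    }
    out[k] <- q$value / T_
  }
  out
}

# Evaluate one bridge's occupancy on the full grid with Gauss-Legendre
# quadrature in t. Each time slice is rasterised by its exact per-cell
# Gaussian mass (pnorm differences along each axis, divided by the cell
# area), which conserves mass even where the slice is much narrower than a
# cell (e.g. near the bridge endpoints).
bridge_occupancy_raster <- function(bridge, ax, cellsize, n_nodes = 61) {
  b <- bridge_fields(bridge)
  T_ <- b$median_duration
  gl <- pracma::gaussLegendre(n_nodes, 0, T_)
  nx <- length(ax$x); ny <- length(ax$y)
  acc <- matrix(0, nrow = ny, ncol = nx)
  h <- cellsize / 2
  for (k in seq_along(gl$x)) {
    t1 <- gl$x[k]
    s <- sqrt(bridge_variance(t1, bridge))
    mx <- b$x1 + (t1 / T_) * (b$x2 - b$x1)
    my <- b$y1 + (t1 / T_) * (b$y2 - b$y1)
    gx <- stats::pnorm(ax$x + h, mx, s) - stats::pnorm(ax$x - h, mx, s)
    gy <- stats::pnorm(ax$y + h, my, s) - stats::pnorm(ax$y - h, my, s)
    acc <- acc + (gl$w[k] / cellsize^2) * (gy %o% gx)
  }
  acc / T_
}

#' Grid specification covering a bridge set
#'
#' Convenience constructor for the raster geometry: a square-cell grid
#' covering all bridge endpoints with a margin of `margin_sd` times the
#' largest positional scale of any bridge (endpoint spread plus diffusive
#' spread at mid-transit), so that the occupancy mass leaking off the
#' raster is negligible.
#'
#' @param bridges A `bridge_set` (see [build_bridges()]).
#' @param cellsize Cell side in metres (default 0.05).
#' @param margin_sd Margin width in units of the largest positional SD.
#' @return A list with `x0`, `y0`, `cellsize`, `nx`, `ny`.
#' @export
grid_spec_for <- function(bridges, cellsize = 0.05, margin_sd = 4) {
  assert_scalar_number(cellsize, "cellsize", positive = TRUE)
  smax <- sqrt(max(
    bridges$sigma_s2, bridges$sigma_e2,
    2 * bridges$diffusion * bridges$median_duration / 4 +
      pmax(bridges$sigma_s2, bridges$sigma_e2)
  ))
  margin <- margin_sd * smax
  x_rng <- range(c(bridges$x1, bridges$x2)) + c(-margin, margin)
  y_rng <- range(c(bridges$y1, bridges$y2)) + c(-margin, margin)
  list(
    x0 = x_rng[1], y0 = y_rng[1], cellsize = cellsize,
    nx = ceiling(diff(x_rng) / cellsize),
    ny = ceiling(diff(y_rng) / cellsize)
  )
}

#' Population occupancy raster
#'
#' Sums the occupancy densities of all bridges, weighted by their crossing
#' counts, into a single stationary spatial density, stored as the exact
#' cell-average of the density (so the raster conserves probability mass
#' even where a bridge's footprint is narrower than a cell):
#' \deqn{P = \sum_b f_b\,\rho_b \Big/ \sum_b f_b .}
#' The raster must hold (almost) all the mass: the function checks that the
#' total cell mass is 1 within `mass_tol` and that no more than 1% of the
#' mass sits in the outermost cell ring, and errors otherwise (enlarge the
#' grid or refine the cells).
#'
#' @param bridges A `bridge_set` with at least one row.
#' @param grid_spec Raster geometry from [grid_spec_for()] (or a compatible
#'   list).
#' @param n_nodes Number of Gauss-Legendre nodes for the time quadrature.
#' @param mass_tol Tolerance on the total raster mass.
#' @return A [landscape_grid()] holding the occupancy density P (1/m^2).
#' @export
population_occupancy <- function(bridges, grid_spec = grid_spec_for(bridges),
                                 n_nodes = 61, mass_tol = 1e-3) {
  if (nrow(bridges) < 1) abort("At least one bridge is required.")
  ax <- list(
    x = grid_spec$x0 + (seq_len(grid_spec$nx) - 0.5) * grid_spec$cellsize,
    y = grid_spec$y0 + (seq_len(grid_spec$ny) - 0.5) * grid_spec$cellsize
  )
  total <- matrix(0, nrow = grid_spec$ny, ncol = grid_spec$nx)
  wsum <- sum(bridges$n_cross)
  for (k in seq_len(nrow(bridges))) {
    total <- total + bridges$n_cross[k] *
      bridge_occupancy_raster(bridges[k, ], ax, grid_spec$cellsize,
                              n_nodes = n_nodes)
  }
  total <- total / wsum
  area <- grid_spec$cellsize^2
  mass <- sum(total) * area
  if (abs(mass - 1) > mass_tol) {
    abort(sprintf("Occupancy raster mass is %.6f (tolerance %g): grid too small or cells too coarse.",
                  mass, mass_tol))
  }
  ring <- sum(total[1, ], total[nrow(total), ],
              total[-c(1, nrow(total)), 1], total[-c(1, nrow(total)), ncol(total)]) * area
  if (ring > 0.01) {
    abort(sprintf("%.2f%% of the occupancy mass lies on the raster boundary (> 1%%): grid too small.",
                  100 * ring))
  }
  landscape_grid(total, x0 = grid_spec$x0, y0 = grid_spec$y0,
                 cellsize = grid_spec$cellsize)
}

#' Dynamic landscape from an occupancy density
#'
#' Inverts the stationary density into a potential surface. A stationary
#' density P and its potential u are linked by \eqn{P \propto e^{-u}} (in
#' `k_B T = 1` units), so \eqn{u_d = -\ln(P / P_{max})}: the most-used cell
#' sits at height 0 and less-used cells are higher. Cells with density
#' below `floor_frac * max(P)` are capped at `-ln(floor_frac)` so the
#' raster stays finite.
#'
#' @param P A [landscape_grid()] of occupancy density (from
#'   [population_occupancy()]).
#' @param floor_frac Density floor as a fraction of the maximum (default
#'   1e-12, giving a height ceiling of about 27.6).
#' @return A [landscape_grid()] with the dynamic landscape `u_d`.
#' @export
dynamic_landscape <- function(P, floor_frac = 1e-12) {
  stopifnot(inherits(P, "landscape_grid"))
  v <- P$values
  if (any(v < 0, na.rm = TRUE)) abort("Occupancy density must be >= 0.")
  pmax_val <- max(v, na.rm = TRUE)
  if (!is.finite(pmax_val) || pmax_val <= 0) abort("Occupancy density is all zero.")
  u <- -log(pmax(v / pmax_val, floor_frac))
  landscape_grid(u, x0 = P$x0, y0 = P$y0, cellsize = P$cellsize)
}
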