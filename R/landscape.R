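#' Assemble the perceptual landscape
#'
#' Adds the dynamic landscape (from movement bridges) and the nesting
#' landscape (from residence wells) cell-wise:
#' \deqn{u = u_d + u_w.}
#' Both rasters must share the same geometry. The result is defined up to
#' an additive constant, so comparisons should always be of height
#' differences.
#'
#' @param u_d,u_w [landscape_grid()] objects on identical geometry.
#' @return A [landscape_grid()] with the combined landscape.
#' @export
assemble_landscape <- function(u_d, u_w) {
  stopifnot(inherits(u_d, "landscape_grid"), inherits(u_w, "landscape_grid"))
  same <- identical(dim(u_d$values), dim(u_w$values)) &&
    isTRUE(all.equal(c(u_d$x0, u_d$y0, u_d$cellsize),
                     c(u_w$x0, u_w$y0, u_w$cellsize), tolerance = 1e-12))
  if (!same) {
    abort(sprintf(
      "Grid geometries differ: u_d is %dx%d @ %g m from (%g, %g); u_w is %dx%d @ %g m from (%g, %g).",
      nrow(u_d$values), ncol(u_d$values), u_d$cellsize, u_d$x0, u_d$y0,
      nrow(u_w$values), ncol(u_w$values), u_w$cellsize, u_w$x0, u_w$y0))
  }
  landscape_grid(u_d$values + u_w$values, x0 = u_d$x0, y0 = u_d$y0,
                 cellsize = u_d$cellsize)
}

#' Build a perceptual landscape from stays
#'
#' End-to-end pipeline for a set of stays: derive transits, summarise
#' bridges, calibrate (or reuse) the effective speed, build the dynamic
#' landscape from weighted Brownian-bridge occupancy, build the nesting
#' landscape from residence wells, and add the two.
#'
#' @param stays Stay table.
#' @param layout Site layout.
#' @param min_crossings Bridge crossing filter (default 50).
#' @param vbar Effective speed; `NULL` (default) calibrates it from these
#'   bridges via [calibrate_vbar()].
#' @param cellsize Raster cell size, metres.
#' @param gamma,omega0,omega_b Well shape parameters (see [well_depth()]).
#' @param grid_spec Optional raster geometry; defaults to a grid covering
#'   the bridges with margin (see [grid_spec_for()]).
#' @param n_nodes Time-quadrature nodes for the occupancy raster.
#' @return A list of class `perceptual_landscape` with elements `u`
#'   (combined), `u_d`, `u_w` (all [landscape_grid()]), `bridges`
#'   (the `bridge_set`), `vbar`, `D_bar` and `D_r`.
#' @export
build_landscape <- function(stays, layout, min_crossings = 50, vbar = NULL,
                            cellsize = 0.05, gamma = 1, omega0 = 1,
                            omega_b = 1, grid_spec = NULL, n_nodes = 61) {
  transits <- stays_to_transits(stays)
  bs <- bridge_summary(transits, layout, min_crossings = min_crossings)
  if (nrow(bs) == 0) {
    abort("No bridge survives the crossing filter; lower `min_crossings`.")
  }
  if (is.null(vbar)) vbar <- calibrate_vbar(bs)
  bridges <- build_bridges(bs, layout, vbar)
  if (is.null(grid_spec)) grid_spec <- grid_spec_for(bridges, cellsize = cellsize)
  P <- population_occupancy(bridges, grid_spec, n_nodes = n_nodes)
  u_d <- dynamic_landscape(P)
  D_bar <- weighted_mean_diffusion(bridges)
  D_r <- radial_diffusion(D_bar)
  u_w <- nesting_landscape(stays, layout, D_r, grid_spec, gamma = gamma,
                           omega0 = omega0, omega_b = omega_b)
  structure(list(u = assemble_landscape(u_d, u_w), u_d = u_d, u_w = u_w,
                 occupancy = P, bridges = bridges, vbar = vbar,
                 D_bar = D_bar, D_r = D_r),
            class = "perceptual_landscape")
}

#' @export
print.perceptual_landscape <- function(x, ...) {
  cat("<perceptual_landscape>\n")
  cat(sprintf("  %d bridges, vbar = %.4g m/s, D_bar = %.4g m^2/s, D_r = %.4g m^2/s\n",
              nrow(x$bridges), x$vbar, x$D_bar, x$D_r))
  print(x$u)
  invisible(x)
}

#' Perceptual landscape of a single animal
#'
#' Runs the full landscape pipeline restricted to one animal's stays and
#' transits, with a lower default crossing filter (10, reflecting the
#' smaller per-animal sample). The effective speed is *not* re-calibrated
#' per animal: pass the population `vbar` so that diffusion coefficients
#' mean the same thing across individual landscapes.
#'
#' @param stays Stay table for the whole dataset.
#' @param layout Site layout.
#' @param animal_id Identifier of the focal animal.
#' @param vbar Population-level effective speed ([calibrate_vbar()]).
#' @param min_crossings Per-animal bridge filter (default 10).
#' @param ... Further arguments passed to [build_landscape()].
#' @return A `perceptual_landscape` (see [build_landscape()]).
#' @export
individual_landscape <- function(stays, layout, animal_id, vbar,
                                 min_crossings = 10, ...) {
  s <- stays[stays$animal_id == animal_id, ]
  if (nrow(s) == 0) abort(sprintf("No stays recorded for animal %s.", animal_id))
  tr <- stays_to_transits(s)
  bs <- bridge_summary(tr, layout, min_crossings = min_crossings)
  if (nrow(bs) == 0) {
    abort(sprintf("No bridge of animal %s survives min_crossings = %d; try a lower threshold.",
                  animal_id, min_crossings))
  }
  build_landscape(s, layout, min_crossings = min_crossings, vbar = vbar, ...)
}
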