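#' Frequency-weighted mean diffusion coefficient
#'
#' Averages the per-bridge diffusion coefficients weighted by crossing
#' counts, giving the typical diffusive intensity of an animal on the move.
#'
#' @param bridges A `bridge_set` with columns `diffusion` and `n_cross`.
#' @return Mean diffusion coefficient, m^2/s.
#' @export
weighted_mean_diffusion <- function(bridges) {
  assert_columns(bridges, c("diffusion", "n_cross"))
  if (nrow(bridges) == 0) abort("At least one bridge is required.")
  sum(bridges$diffusion * bridges$n_cross) / sum(bridges$n_cross)
}

#' Radial diffusion coefficient
#'
#' Inside a well the motion is purely diffusive; the radial coordinate
#' collects the independent diffusion of both planar axes, so
#' `D_r = 2 * D_bar`.
#'
#' @param D_bar Mean planar diffusion coefficient, m^2/s.
#' @return Radial diffusion coefficient, m^2/s.
#' @export
radial_diffusion <- function(D_bar) {
  if (any(D_bar < 0)) abort("`D_bar` must be >= 0.")
  2 * D_bar
}

#' Well depth from mean residence time
#'
#' Inverts the Kramers/Klein escape law for a particle diffusing in a
#' single circular well: an observed mean residence time `tau` corresponds
#' to a well of depth
#' \deqn{\Delta u = \gamma D_r \ln\!\big(\omega_0\omega_b\,\tau / (2\pi\gamma)\big),}
#' clipped below at zero. Depth grows logarithmically with residence time
#' and linearly with the diffusion inside the well: a site only counts as
#' deeply attractive if animals stay far longer than free diffusion across
#' it would take.
#'
#' @param tau Mean residence time(s), seconds (vectorised).
#' @param D_r Radial diffusion coefficient, m^2/s.
#' @param gamma Friction scale (default 1; pure height scaling).
#' @param omega0,omega_b Bottom and rim curvature frequencies, 1/s
#'   (default 1).
#' @return Well depth(s), same length as `tau`.
#' @export
well_depth <- function(tau, D_r, gamma = 1, omega0 = 1, omega_b = 1) {
  if (any(tau <= 0)) abort("`tau` must be > 0.")
  assert_scalar_number(D_r, "D_r", positive = TRUE)
  assert_scalar_number(gamma, "gamma", positive = TRUE)
  assert_scalar_number(omega0, "omega0", positive = TRUE)
  assert_scalar_number(omega_b, "omega_b", positive = TRUE)
  pmax(gamma * D_r * log(omega0 * omega_b * tau / (2 * pi * gamma)), 0)
}

#' Construct a potential well
#'
#' Builds the radial profile of a single site's potential well: depth
#' `-depth` at the centre, 0 at the rim `r = a`, stationary (zero slope) at
#' both, and monotone non-decreasing in between. The profile is quadratic
#' near both stationary points, with curvatures `gamma * omega^2 / 4`
#' (the curvature convention under which the Euler-Maruyama escape time
#' from the constructed well matches the `2*pi*gamma/(omega0*omega_b)`
#' escape-law prefactor used by [well_depth()]; see the package vignette),
#' joined by a monotone cubic Hermite segment. Given the radius, the whole
#' construction is governed by the depth alone when the curvature defaults
#' are kept.
#'
#' @param centre Numeric length-2, well centre (x, y) in metres.
#' @param a Well radius, metres.
#' @param depth Well depth (>= 0).
#' @inheritParams well_depth
#' @return An object of class `potential_well`.
#' @export
potential_well <- function(centre, a, depth, gamma = 1, omega0 = 1, omega_b = 1) {
  if (length(centre) != 2 || !all(is.finite(centre))) {
    abort("`centre` must be two finite coordinates.")
  }
  assert_scalar_number(a, "a", positive = TRUE)
  assert_scalar_number(depth, "depth", nonneg = TRUE)
  k0 <- gamma * omega0^2 / 4
  kb <- gamma * omega_b^2 / 4
  geom <- well_geometry(depth, a, k0, kb)
  structure(c(list(centre = as.numeric(centre), a = a, depth = depth,
                   gamma = gamma, omega0 = omega0, omega_b = omega_b,
                   k0 = k0, kb = kb), geom),
            class = "potential_well")
}

# Cap extents and Hermite data for the piecewise radial profile.
# Caps may climb at most half the depth each; extents shrink until the
# middle cubic Hermite segment is guaranteed monotone (Fritsch-Carlson
# sufficient condition: end slopes <= 3 * secant slope).
well_geometry <- function(depth, a, k0, kb) {
  if (depth == 0) {
    return(list(r0 = a / 2, r1 = a / 2, u0 = 0, u1 = 0, s0 = 0, s1 = 0))
  }
  e0 <- min(sqrt(depth / k0), 0.45 * a)
  e1 <- min(sqrt(depth / kb), 0.45 * a)
  if (e0 + e1 > a) {
    if (abs((e0 + e1) - a) < 1e-9 * a) {
      # caps meet tangentially: pure two-quadratic profile
      return(list(r0 = e0, r1 = e0,
                  u0 = -depth + k0 * e0^2 / 2, u1 = -kb * e1^2 / 2,
                  s0 = k0 * e0, s1 = kb * e1))
    }
    sc <- 0.45 * a / max(e0, e1)
    e0 <- e0 * sc; e1 <- e1 * sc
  }
  r0 <- e0; r1 <- a - e1
  repeat {
    u0 <- -depth + k0 * r0^2 / 2
    u1 <- -kb * (a - r1)^2 / 2
    s0 <- k0 * r0
    s1 <- kb * (a - r1)
    if (r1 - r0 < 1e-12 * a) break
    dm <- (u1 - u0) / (r1 - r0)
    if (dm > 0 && s0 <= 3 * dm && s1 <= 3 * dm) break
    r0 <- r0 / 2
    r1 <- a - (a - r1) / 2
  }
  list(r0 = r0, r1 = r1, u0 = u0, u1 = u1, s0 = s0, s1 = s1)
}

#' Evaluate a well's radial profile
#'
#' @param r Radial distance(s) from the well centre, metres (>= 0).
#' @param well A [potential_well()].
#' @param deriv If `TRUE`, return the radial derivative du/dr instead.
#' @return Potential (or derivative) values; 0 for `r >= a`.
#' @export
well_profile <- function(r, well, deriv = FALSE) {
  stopifnot(inherits(well, "potential_well"))
  if (any(r < 0)) abort("`r` must be >= 0.")
  w <- well
  u <- numeric(length(r))
  if (w$depth == 0) return(u)
  inside <- r < w$a
  lo <- inside & r <= w$r0
  hi <- inside & r >= w$r1
  mid <- inside & !lo & !hi
  if (deriv) {
    u[lo] <- w$k0 * r[lo]
    u[hi] <- w$kb * (w$a - r[hi])
    if (any(mid)) {
      h <- w$r1 - w$r0
      tt <- (r[mid] - w$r0) / h
      u[mid] <- (6 * tt^2 - 6 * tt) / h * w$u0 + (3 * tt^2 - 4 * tt + 1) * w$s0 +
        (-6 * tt^2 + 6 * tt) / h * w$u1 + (3 * tt^2 - 2 * tt) * w$s1
    }
  } else {
    u[lo] <- -w$depth + w$k0 * r[lo]^2 / 2
    u[hi] <- -w$kb * (w$a - r[hi])^2 / 2
    if (any(mid)) {
      h <- w$r1 - w$r0
      tt <- (r[mid] - w$r0) / h
      h00 <- 2 * tt^3 - 3 * tt^2 + 1
      h10 <- tt^3 - 2 * tt^2 + tt
      h01 <- -2 * tt^3 + 3 * tt^2
      h11 <- tt^3 - tt^2
      u[mid] <- h00 * w$u0 + h * h10 * w$s0 + h01 * w$u1 + h * h11 * w$s1
    }
  }
  u
}

#' Mean escape time from a well, by quadrature
#'
#' Exact mean first-passage time of an overdamped particle started at the
#' well centre, reflected at `r = 0` and absorbed at the rim `r = a`,
#' computed from the classical double-integral formula for one-dimensional
#' diffusion in a potential. Serves as a deterministic oracle for the
#' escape-law inversion in [well_depth()].
#'
#' @param well A [potential_well()].
#' @param D_r Radial diffusion coefficient, m^2/s.
#' @param n Number of grid points for the nested trapezoidal quadrature.
#' @return Mean escape time, seconds.
#' @export
well_escape_time_quad <- function(well, D_r, n = 20001) {
  assert_scalar_number(D_r, "D_r", positive = TRUE)
  r <- seq(0, well$a, length.out = n)
  phi <- well_profile(r, well) / (well$gamma * D_r)
  h <- r[2] - r[1]
  m <- min(phi)
  em <- exp(-(phi - m))
  inner <- (cumsum(em) - em / 2 - em[1] / 2) * h
  ep <- exp(phi - m)
  f <- ep * inner
  sum(f[-1] + f[-n]) / 2 * h / D_r
}

#' Simulate escapes from a well (Euler-Maruyama)
#'
#' Monte-Carlo oracle for the escape law: integrates the overdamped radial
#' Langevin equation
#' \deqn{dr = -u'(r)/\gamma \, dt + \sqrt{2 D_r}\, dW}
#' with reflection at `r = 0` and absorption at `r = a`, starting all
#' replicates at the well centre, and returns the first-passage times.
#' Uses R's random number stream (set a seed for reproducibility).
#'
#' @param well A [potential_well()].
#' @param D_r Radial diffusion coefficient, m^2/s.
#' @param n_rep Number of replicates.
#' @param dt Integration step, seconds.
#' @param max_steps Safety cap on steps per replicate.
#' @return Numeric vector of `n_rep` escape times, seconds.
#' @export
simulate_escape <- function(well, D_r, n_rep = 1000, dt = 0.02,
                            max_steps = 1e9) {
  stopifnot(inherits(well, "potential_well"))
  assert_scalar_number(D_r, "D_r", positive = TRUE)
  assert_scalar_number(dt, "dt", positive = TRUE)
  escape_times_cpp(
    as.integer(n_rep), dt, D_r, well$gamma, well$a,
    well$r0, well$r1, well$k0, well$kb, well$depth,
    well$u0, well$u1, well$s0, well$s1, as.double(max_steps)
  )
}

#' Nesting landscape from site residence times
#'
#' Builds one potential well per site with recorded stays: the well depth
#' is obtained by inverting the escape law ([well_depth()]) at the site's
#' *mean* stay duration (the escape time is itself a mean first-passage
#' time), the well radius is the site's layout radius, and all wells are
#' summed onto the raster. Sites with no stays contribute no well and are
#' reported.
#'
#' @param stays Stay table.
#' @param layout Site layout (every site in `stays` must appear).
#' @param D_r Radial diffusion coefficient, m^2/s (see
#'   [radial_diffusion()]).
#' @param grid_spec Raster geometry (list with `x0`, `y0`, `cellsize`,
#'   `nx`, `ny`), e.g. from [grid_spec_for()].
#' @inheritParams well_depth
#' @return A [landscape_grid()] with the nesting landscape `u_w`.
#' @export
nesting_landscape <- function(stays, layout, D_r, grid_spec,
                              gamma = 1, omega0 = 1, omega_b = 1) {
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"))
  validate_layout(layout)
  unknown <- setdiff(unique(stays$site_id), layout$site_id)
  if (length(unknown) > 0) {
    abort(sprintf("Site(s) %s appear in stays but not in the layout.",
                  paste(unknown, collapse = ", ")))
  }
  if (any(grid_spec$cellsize > layout$radius / 5)) {
    warn(sprintf("Cell size %g m exceeds radius/5 for some sites; well caps may be under-resolved.",
                 grid_spec$cellsize))
  }
  ax <- list(
    x = grid_spec$x0 + (seq_len(grid_spec$nx) - 0.5) * grid_spec$cellsize,
    y = grid_spec$y0 + (seq_len(grid_spec$ny) - 0.5) * grid_spec$cellsize
  )
  u <- matrix(0, nrow = grid_spec$ny, ncol = grid_spec$nx)
  tau_by_site <- stays |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(tau = mean(.data$t_out - .data$t_in), .groups = "drop")
  skipped <- setdiff(layout$site_id, tau_by_site$site_id)
  if (length(skipped) > 0) {
    inform(sprintf("nesting_landscape: no stays at site(s) %s; no well built there.",
                   paste(skipped, collapse = ", ")))
  }
  for (k in seq_len(nrow(tau_by_site))) {
    i <- match(tau_by_site$site_id[k], layout$site_id)
    depth <- well_depth(tau_by_site$tau[k], D_r, gamma = gamma,
                        omega0 = omega0, omega_b = omega_b)
    w <- potential_well(c(layout$x[i], layout$y[i]), layout$radius[i], depth,
                        gamma = gamma, omega0 = omega0, omega_b = omega_b)
    dx2 <- (ax$x - layout$x[i])^2
    dy2 <- (ax$y - layout$y[i])^2
    near_x <- which(dx2 <= layout$radius[i]^2)
    near_y <- which(dy2 <= layout$radius[i]^2)
    if (length(near_x) == 0 || length(near_y) == 0) next
    rr <- sqrt(outer(dy2[near_y], dx2[near_x], `+`))
    u[near_y, near_x] <- u[near_y, near_x] + well_profile(pmin(rr, w$a), w)
  }
  landscape_grid(u, x0 = grid_spec$x0, y0 = grid_spec$y0,
                 cellsize = grid_spec$cellsize)
}
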