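test_that("diffusion coefficient follows the arrival-condition algebra", {
  # straight-line bridge: no diffusion left over
  expect_equal(bridge_diffusion(2, 100, 0.02), 0)

  # stationary transit (L = 0): all effective motion is diffusion;
  # frozen against the mean-square-displacement identity 4DT = (vbar*T)^2
  D0 <- bridge_diffusion(0, 100, 0.02)
  expect_equal(D0, 0.01)
  expect_equal(4 * D0 * 100, (0.02 * 100)^2)

  # doubling vbar more than doubles D when L > 0
  D1 <- bridge_diffusion(1, 100, 0.02)
  D2 <- bridge_diffusion(1, 100, 0.04)
  expect_gt(D2 / D1, 2)

  # monotone increasing in vbar at fixed (L, T)
  v <- seq(0.011, 0.05, length.out = 20)
  Ds <- vapply(v, function(vv) bridge_diffusion(1, 100, vv), numeric(1))
  expect_true(all(diff(Ds) > 0))

  expect_error(bridge_diffusion(3, 100, 0.02), "calibrated")
  expect_error(bridge_diffusion(1, -5, 0.02), "duration")
})

test_that("Euler-Maruyama displacement matches the calibration identity", {
  # independent oracle: integrate the Langevin motion (constant drift L/T
  # plus isotropic diffusion D) and check the arrival-condition MSD
  # <d^2(T)> = L^2 + 4DT = (vbar T)^2 used to define D.
  set.seed(101)
  vbar <- 0.02; L <- 1.2; T_ <- 150
  D <- bridge_diffusion(L, T_, vbar)
  n <- 20000; steps <- 200; dt <- T_ / steps
  x <- matrix(0, n, 2)
  drift <- c(L / T_, 0)
  for (k in seq_len(steps)) {
    x <- x + matrix(drift, n, 2, byrow = TRUE) * dt +
      sqrt(2 * D * dt) * matrix(rnorm(2 * n), n, 2)
  }
  msd <- mean(rowSums(x^2))
  expect_lt(abs(msd / (vbar * T_)^2 - 1), 0.03)
})

test_that("bridge variance interpolates endpoint errors and peaks at T/2", {
  br <- one_bridge(T_ = 100, D = 0.005, s2 = 0.01)
  expect_equal(bridge_variance(0, br), 0.01)
  expect_equal(bridge_variance(100, br), 0.01)

  # pure bridge closed form at mid-transit: 2 D (T/2) (1/2) = D T / 2
  br0 <- one_bridge(T_ = 100, D = 0.005, s2 = 0)
  expect_equal(bridge_variance(50, br0), 0.005 * 100 / 2)

  # numerical argmax sits at T/2 for symmetric endpoints
  tgrid <- seq(0, 100, by = 0.01)
  expect_equal(tgrid[which.max(bridge_variance(tgrid, br))], 50,
               tolerance = 1e-3)

  expect_error(bridge_variance(101, br), "within")
})

test_that("bridge pdf is a normalised moving Gaussian", {
  br <- one_bridge(T_ = 100, D = 0.005, s2 = 0.01)
  t1 <- 30
  s2 <- bridge_variance(t1, br)
  mx <- br$x1 + t1 / 100 * (br$x2 - br$x1)
  expect_equal(bridge_pdf(mx, 0, t1, br), 1 / (2 * pi * s2))

  # plane integral at mid-transit (tensor Gauss-Legendre quadrature)
  s_mid <- sqrt(bridge_variance(50, br))
  glx <- pracma::gaussLegendre(180, 1 - 8 * s_mid, 1 + 8 * s_mid)
  gly <- pracma::gaussLegendre(180, -8 * s_mid, 8 * s_mid)
  xg <- rep(glx$x, times = 180); yg <- rep(gly$x, each = 180)
  wg <- rep(glx$w, times = 180) * rep(gly$w, each = 180)
  I <- sum(wg * bridge_pdf(xg, yg, 50, br))
  expect_equal(I, 1, tolerance = 1e-6)
})

test_that("bridge pdf matches simulated conditioned-diffusion positions", {
  set.seed(202)
  br <- one_bridge(T_ = 100, D = 0.004, s2 = 0.02)
  pos <- simulate_bridge_positions(br, n_paths = 1e5, t_stop = 50,
                                   n_steps = 1000)
  s2 <- bridge_variance(50, br)
  p <- chisq_gof_gaussian(pos, mx = 1, my = 0, s2 = s2)
  expect_gt(p, 0.01)
})

test_that("bridge occupancy normalises, is symmetric, and matches Monte Carlo", {
  br <- one_bridge(T_ = 100, D = 0.004, s2 = 0.02)

  # raster mass (exact per-cell Gaussian masses, fine time quadrature)
  gs <- grid_spec_for(br, cellsize = 0.04)
  P <- population_occupancy(br, gs, mass_tol = 1e-4)
  expect_equal(sum(P$values) * gs$cellsize^2, 1, tolerance = 1e-4)

  # mirror symmetry through the bridge midpoint for equal endpoints
  pts_x <- c(0.3, 0.8, 1.1, 1.9); pts_y <- c(0.1, -0.2, 0.05, 0)
  d1 <- bridge_occupancy(pts_x, pts_y, br)
  d2 <- bridge_occupancy(2 - pts_x, -pts_y, br)
  expect_equal(d1, d2, tolerance = 1e-8)

  # quadrature path agrees with the raster path
  ax <- list(x = gs$x0 + (seq_len(gs$nx) - 0.5) * gs$cellsize,
             y = gs$y0 + (seq_len(gs$ny) - 0.5) * gs$cellsize)
  ix <- vapply(pts_x, function(p) which.min(abs(ax$x - p)), integer(1))
  iy <- vapply(pts_y, function(p) which.min(abs(ax$y - p)), integer(1))
  expect_equal(d1, P$values[cbind(iy, ix)], tolerance = 0.02)

  # time-pooled Monte-Carlo positions against the occupancy density
  set.seed(303)
  n_paths <- 1e5
  tt <- seq_len(512) / 512 * 100 - 100 / 1024  # mid-step grid
  t_pick <- sample(tt, n_paths, replace = TRUE)
  # simulate each path only to its own pooled time, in batches by time
  pos <- matrix(NA_real_, n_paths, 2)
  for (t1 in unique(t_pick)) {
    idx <- which(t_pick == t1)
    pos[idx, ] <- simulate_bridge_positions(br, length(idx), t1,
                                            n_steps = 60)
  }
  # occupancy probability of each cell of a 10x10 grid via the raster
  brk <- seq(0.6, 1.4, length.out = 11)  # central band across the bridge
  ybrk <- seq(-0.4, 0.4, length.out = 11)
  cell_prob <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    xs <- ax$x >= brk[i] & ax$x < brk[i + 1]
    ys <- ax$y >= ybrk[j] & ax$y < ybrk[j + 1]
    cell_prob[i, j] <- sum(P$values[ys, xs]) * gs$cellsize^2
  }
  ix <- findInterval(pos[, 1], brk)
  iy <- findInterval(pos[, 2], ybrk)
  inside <- ix >= 1 & ix <= 10 & iy >= 1 & iy <= 10
  obs <- table(factor(ix[inside], 1:10), factor(iy[inside], 1:10))
  obs_v <- c(as.vector(t(obs)), sum(!inside))
  p_v <- c(as.vector(t(cell_prob)), 1 - sum(cell_prob))
  keep <- p_v * n_paths >= 5
  chi2 <- sum((obs_v[keep] - n_paths * p_v[keep])^2 / (n_paths * p_v[keep]))
  p_val <- stats::pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p_val, 0.01)
})

test_that("population occupancy is a normalised weighted sum", {
  br <- one_bridge(T_ = 80, D = 0.003, s2 = 0.02)
  gs <- grid_spec_for(br, cellsize = 0.05)
  single <- population_occupancy(br, gs)

  # two identical bridges with weights (1, 3) equal the weight-(1, 1) case
  two_a <- dplyr::bind_rows(br, dplyr::mutate(br, n_cross = 3L))
  two_b <- dplyr::bind_rows(br, br)
  expect_equal(population_occupancy(two_a, gs)$values,
               population_occupancy(two_b, gs)$values)
  expect_equal(population_occupancy(two_a, gs)$values, single$values)

  # random 5-bridge system conserves mass
  set.seed(55)
  many <- dplyr::bind_rows(lapply(1:5, function(k) {
    one_bridge(x1 = runif(1, 0, 1), y1 = runif(1, 0, 1),
               x2 = runif(1, 1, 2), y2 = runif(1, 1, 2),
               T_ = runif(1, 50, 150), D = runif(1, 1e-3, 5e-3),
               s2 = 0.02, f = sample(1:20, 1))
  }))
  gs5 <- grid_spec_for(many, cellsize = 0.05)
  P5 <- population_occupancy(many, gs5)
  expect_equal(sum(P5$values) * gs5$cellsize^2, 1, tolerance = 1e-3)

  # a grid that clips the density is refused
  gs_small <- gs5
  gs_small$nx <- ceiling(gs_small$nx / 3)
  expect_error(population_occupancy(many, gs_small), "mass|boundary")
})

test_that("low-diffusion occupancy concentrates on the segment", {
  br <- one_bridge(T_ = 100, D = 1e-5, s2 = 1e-4)
  gs <- grid_spec_for(br, cellsize = 0.01)
  P <- population_occupancy(br, gs)
  ax <- list(x = gs$x0 + (seq_len(gs$nx) - 0.5) * gs$cellsize,
             y = gs$y0 + (seq_len(gs$ny) - 0.5) * gs$cellsize)
  tube <- abs(ax$y) <= 0.1
  expect_gt(sum(P$values[tube, ]) / sum(P$values), 0.99)
  # ridge of each column within the tube (mode on the segment)
  on_seg <- ax$x >= 0 & ax$x <= 2
  ridge_y <- ax$y[apply(P$values[, on_seg], 2, which.max)]
  expect_true(all(abs(ridge_y) <= 0.05))
})

test_that("landscape inversion is the negative log of relative density", {
  g <- landscape_grid(matrix(c(1, 1, 1, 1), 2, 2), 0, 0, 1)
  expect_equal(dynamic_landscape(g)$values, matrix(0, 2, 2))

  g2 <- landscape_grid(matrix(c(exp(1), 1, 1, 1), 2, 2), 0, 0, 1)
  u2 <- dynamic_landscape(g2)$values
  expect_equal(u2[2, 1] - u2[1, 1], 1)

  # argmax/argmin duality and monotone duality on a random raster
  set.seed(66)
  v <- matrix(rexp(400), 20, 20)
  u <- dynamic_landscape(landscape_grid(v, 0, 0, 0.1))$values
  expect_equal(which.min(u), which.max(v))
  expect_equal(min(u), 0)
  v2 <- v; v2[7, 7] <- v2[7, 7] * 2
  u_after <- dynamic_landscape(landscape_grid(v2, 0, 0, 0.1))$values
  expect_lte(u_after[7, 7], u[7, 7])

  # density floor caps the height
  v3 <- v; v3[1, 1] <- 0
  u3 <- dynamic_landscape(landscape_grid(v3, 0, 0, 0.1))$values
  expect_equal(u3[1, 1], -log(1e-12))
  expect_error(dynamic_landscape(landscape_grid(matrix(0, 2, 2), 0, 0, 1)),
               "zero")
})
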