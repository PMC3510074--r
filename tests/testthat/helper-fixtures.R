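# Small in-code fixtures shared across test files.

tiny_layout <- function(n = 3, radius = 0.05, spacing = 2) {
  tibble::tibble(
    site_id = sprintf("B%d", seq_len(n)),
    x = (seq_len(n) - 1) * spacing,
    y = rep(0, n),
    radius = radius
  )
}

tiny_stays <- function() {
  tibble::tibble(
    animal_id = c("a", "a", "a", "b", "b"),
    site_id = c("B1", "B2", "B1", "B1", "B3"),
    t_in = c(0, 20, 50, 5, 40),
    t_out = c(10, 30, 70, 15, 60)
  )
}

# A single bridge row in bridge_set form.
one_bridge <- function(x1 = 0, y1 = 0, x2 = 2, y2 = 0, T_ = 100,
                       D = 0.005, s2 = 0.01, f = 1) {
  tibble::tibble(
    site_a = "B1", site_b = "B2", n_cross = f,
    distance = sqrt((x2 - x1)^2 + (y2 - y1)^2), median_duration = T_,
    x1 = x1, y1 = y1, x2 = x2, y2 = y2,
    diffusion = D, sigma_s2 = s2, sigma_e2 = s2
  )
}

# Euler-Maruyama sampler of the conditioned bridge diffusion: start drawn
# from N(r1, sigma_s2), pinned endpoint drawn from N(r2, sigma_e2), then
# the exact bridge SDE dx = (e - x)/(T - t) dt + sqrt(2D) dW per axis.
# Returns positions at time t_stop. Independent of the closed-form density.
simulate_bridge_positions <- function(bridge, n_paths, t_stop,
                                      n_steps = 400) {
  b <- as.list(bridge[1, ])
  T_ <- b$median_duration
  dt <- t_stop / n_steps
  sq <- sqrt(2 * b$diffusion * dt)
  sim_axis <- function(mu1, mu2, s1, s2) {
    x <- rnorm(n_paths, mu1, sqrt(s1))
    e <- rnorm(n_paths, mu2, sqrt(s2))
    t <- 0
    for (k in seq_len(n_steps)) {
      x <- x + (e - x) / (T_ - t) * dt + sq * rnorm(n_paths)
      t <- t + dt
    }
    x
  }
  cbind(sim_axis(b$x1, b$x2, b$sigma_s2, b$sigma_e2),
        sim_axis(b$y1, b$y2, b$sigma_s2, b$sigma_e2))
}

# chi-square goodness of fit of 2-d positions against per-cell Gaussian
# masses on a grid centred at (mx, my); remaining mass lumped in one cell.
chisq_gof_gaussian <- function(pos, mx, my, s2, half_width = 3,
                               n_bins = 10) {
  s <- sqrt(s2)
  brk <- seq(-half_width * s, half_width * s, length.out = n_bins + 1)
  ix <- findInterval(pos[, 1] - mx, brk, all.inside = FALSE)
  iy <- findInterval(pos[, 2] - my, brk, all.inside = FALSE)
  inside <- ix >= 1 & ix <= n_bins & iy >= 1 & iy <= n_bins
  obs <- table(factor(ix[inside], levels = seq_len(n_bins)),
               factor(iy[inside], levels = seq_len(n_bins)))
  p1 <- diff(pnorm(brk, 0, s))
  pcell <- as.vector(outer(p1, p1))
  obs_v <- as.vector(obs)
  # lump the outside mass
  obs_v <- c(obs_v, sum(!inside))
  pcell <- c(pcell, 1 - sum(pcell))
  n <- nrow(pos)
  keep <- pcell * n >= 5
  chi2 <- sum((obs_v[keep] - n * pcell[keep])^2 / (n * pcell[keep]))
  stats::pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
}
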