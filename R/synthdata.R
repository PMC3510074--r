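#' Generate a synthetic colony with known ground truth
#'
#' Builds a reproducible artificial colony that mimics the structure of a
#' barn population tracked with nest-box antennas: sites grouped into
#' spatial clusters (territory segments), strongly heterogeneous per-box
#' mean residence times, cluster-biased destination preferences, and
#' heavy-tailed (lognormal) transit durations. All generator parameters
#' are recorded in the returned truth object so that estimation stages can
#' be validated against them.
#'
#' Per-box mean residence times follow a shuffled geometric sequence from
#' `tau_min` to `tau_min * heterogeneity`, so the max/min ratio of mean
#' residence times equals `heterogeneity` exactly.
#'
#' @param n_sites Number of sites (>= 2).
#' @param n_animals Number of animals (>= 1).
#' @param duration Observation span, seconds.
#' @param n_clusters Number of spatial clusters.
#' @param tau_min Shortest per-box mean residence time, seconds.
#' @param heterogeneity Ratio of longest to shortest mean residence time.
#' @param within_weight Relative preference for same-cluster destinations.
#' @param self_weight Relative weight of exit-and-return (self) transits.
#' @param transit_scale Baseline transit-time median, seconds.
#' @param transit_speed Distance scaling of transit medians, m/s.
#' @param transit_sdlog Lognormal log-SD of transit durations (heavy tail).
#' @param site_radius Site (well) radius, metres.
#' @param territorial If `TRUE`, each animal is assigned a home cluster and
#'   its destination weights outside that cluster are multiplied by
#'   `1 - territory_strength` (the truth then deviates from the
#'   homogeneous "average animal" model by construction, the way real
#'   territorial populations do).
#' @param territory_strength Strength of territorial confinement in
#'   `[0, 1)`; at 1 the pooled movement graph would disconnect into
#'   per-cluster blocks.
#' @param seed RNG seed; identical `(arguments, seed)` give identical
#'   truth.
#' @return An object of class `colony_truth`: `layout`, `rates` (a
#'   [rate_model()] of truth rates), `transit_meanlog` and
#'   `transit_sdlog` matrices, `tau` (per-box mean residence), `cluster`
#'   (site cluster index), `n_animals`, `duration`, `territorial`,
#'   `animal_cluster`, `seed`.
#' @export
generate_colony <- function(n_sites = 10, n_animals = 12,
                            duration = 30 * 86400, n_clusters = 4,
                            tau_min = 120, heterogeneity = 20,
                            within_weight = 4, self_weight = 1,
                            transit_scale = 60, transit_speed = 0.02,
                            transit_sdlog = 1.2, site_radius = 0.05,
                            territorial = FALSE, territory_strength = 0.95,
                            seed = 1) {
  if (n_sites < 2) abort("At least 2 sites are required.")
  if (n_animals < 1) abort("At least 1 animal is required.")
  assert_scalar_number(duration, "duration", positive = TRUE)
  assert_scalar_number(heterogeneity, "heterogeneity", positive = TRUE)
  n_clusters <- min(n_clusters, n_sites)
  set.seed(seed)

  # layout: cluster centres on a coarse grid, sites jittered inside
  ccol <- ceiling(sqrt(n_clusters))
  centres <- cbind(((seq_len(n_clusters) - 1) %% ccol) * 3,
                   ((seq_len(n_clusters) - 1) %/% ccol) * 3)
  cluster <- rep(seq_len(n_clusters), length.out = n_sites)
  within <- cbind(runif(n_sites, -0.9, 0.9), runif(n_sites, -0.9, 0.9))
  layout <- tibble(
    site_id = sprintf("B%02d", seq_len(n_sites)),
    x = centres[cluster, 1] + within[, 1],
    y = centres[cluster, 2] + within[, 2],
    radius = site_radius
  )

  # residence heterogeneity: shuffled geometric sequence
  tau <- tau_min * heterogeneity^((seq_len(n_sites) - 1) / max(n_sites - 1, 1))
  tau <- sample(tau)

  # destination preferences: cluster-biased with multiplicative jitter
  w <- matrix(1, n_sites, n_sites)
  same <- outer(cluster, cluster, `==`)
  w[same] <- within_weight
  diag(w) <- self_weight
  w <- w * exp(matrix(rnorm(n_sites^2, 0, 0.3), n_sites, n_sites))
  leave <- (1 / tau) * w / rowSums(w)

  d <- as.matrix(stats::dist(cbind(layout$x, layout$y)))
  med <- transit_scale + d / transit_speed
  transit_meanlog <- log(med)
  transit_rate <- 1 / exp(transit_meanlog + transit_sdlog^2 / 2)

  rates <- rate_model(layout$site_id, leave, transit_rate)
  animal_cluster <- if (territorial) {
    rep(seq_len(n_clusters), length.out = n_animals)
  } else NULL
  structure(list(layout = layout, rates = rates,
                 transit_meanlog = transit_meanlog,
                 transit_sdlog = matrix(transit_sdlog, n_sites, n_sites,
                                        dimnames = dimnames(leave)),
                 tau = setNames(tau, layout$site_id), cluster = cluster,
                 n_animals = n_animals, duration = duration,
                 territorial = territorial, animal_cluster = animal_cluster,
                 territory_strength = territory_strength, seed = seed),
            class = "colony_truth")
}

#' @export
print.colony_truth <- function(x, ...) {
  cat(sprintf("<colony_truth> %d sites in %d clusters, %d animals, %.1f days%s (seed %d)\n",
              nrow(x$layout), max(x$cluster), x$n_animals,
              x$duration / 86400, if (x$territorial) ", territorial" else "",
              x$seed))
  cat(sprintf("  mean residence: %.0f-%.0f s (ratio %.1f)\n",
              min(x$tau), max(x$tau), max(x$tau) / min(x$tau)))
  invisible(x)
}

#' Preset colony configurations
#'
#' `"desk"` is the default small configuration used throughout the test
#' suite (10 sites, 12 animals, 30 days; runs in seconds); `"barn"` mirrors
#' the scale of a full two-year barn deployment (40 sites in 4 segments, 76
#' animals, 2 years).
#'
#' @param preset `"desk"` or `"barn"`.
#' @return A named list of [generate_colony()] arguments.
#' @export
colony_preset <- function(preset = c("desk", "barn")) {
  preset <- match.arg(preset)
  switch(preset,
    desk = list(n_sites = 10, n_animals = 12, duration = 30 * 86400,
                n_clusters = 4, heterogeneity = 20),
    barn = list(n_sites = 40, n_animals = 76, duration = 2 * 365 * 86400,
                n_clusters = 4, heterogeneity = 85)
  )
}

#' Simulate ground-truth stays for a colony
#'
#' Draws each animal's trajectory from the truth semi-Markov process:
#' exponential stays at the box's total leave rate, destinations chosen
#' with the departure-rate weights, and *lognormal* transit durations
#' (deliberately heavier-tailed than the exponential transits the null
#' model assumes, as in real data). Trajectories are truncated at the
#' colony duration.
#'
#' @param truth A [generate_colony()] result.
#' @param seed Seed for the trajectory randomness; defaults to
#'   `truth$seed + 1000` so truth and trajectories are independently
#'   reproducible.
#' @return A stay table with animals `"a01"`, `"a02"`, ...
#' @export
generate_stays <- function(truth, seed = truth$seed + 1000) {
  stopifnot(inherits(truth, "colony_truth"))
  set.seed(seed)
  n <- nrow(truth$layout)
  ids <- sprintf("a%02d", seq_len(truth$n_animals))
  out <- vector("list", truth$n_animals)
  for (k in seq_len(truth$n_animals)) {
    leave <- truth$rates$leave
    if (truth$territorial) {
      home <- truth$cluster == truth$animal_cluster[k]
      leave[, !home] <- leave[, !home] * (1 - truth$territory_strength)
      # renormalise rows so each box keeps its total leave rate (= 1/tau)
      leave <- leave / rowSums(leave) * (1 / truth$tau)
      start_pool <- which(home)
    } else {
      start_pool <- seq_len(n)
    }
    cumdest <- apply(leave, 1, cumsum)
    totrate <- rowSums(leave)
    b <- start_pool[sample.int(length(start_pool), 1,
                               prob = truth$tau[start_pool])]
    t <- 0
    cap <- 256L
    site <- integer(cap); t_in <- numeric(cap); t_out <- numeric(cap)
    m <- 0L
    repeat {
      stay <- rexp(1, rate = totrate[b])
      t_end <- min(t + stay, truth$duration)
      if (t_end > t) {
        m <- m + 1L
        if (m > cap) {
          cap <- cap * 2L
          length(site) <- cap; length(t_in) <- cap; length(t_out) <- cap
        }
        site[m] <- b; t_in[m] <- t; t_out[m] <- t_end
      }
      if (t + stay >= truth$duration) break
      t <- t + stay
      j <- findInterval(runif(1) * totrate[b], cumdest[, b],
                        left.open = TRUE) + 1L
      j <- min(j, n)
      t <- t + rlnorm(1, truth$transit_meanlog[b, j], truth$transit_sdlog[b, j])
      if (t >= truth$duration) break
      b <- j
    }
    out[[k]] <- tibble(animal_id = ids[k],
                       site_id = truth$layout$site_id[site[seq_len(m)]],
                       t_in = t_in[seq_len(m)], t_out = t_out[seq_len(m)])
  }
  dplyr::bind_rows(out)
}

#' Serialise stays as a directional antenna event log
#'
#' Converts a stay table into the enter/exit event pairs an antenna system
#' would have produced, time-sorted. `events_to_stays()` inverts this
#' exactly.
#'
#' @param stays Stay table.
#' @return Event tibble (`animal_id`, `site_id`, `direction`,
#'   `timestamp`).
#' @export
stays_to_events <- function(stays) {
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"))
  ev <- dplyr::bind_rows(
    dplyr::transmute(stays, animal_id = .data$animal_id,
                     site_id = .data$site_id, direction = "enter",
                     timestamp = .data$t_in),
    dplyr::transmute(stays, animal_id = .data$animal_id,
                     site_id = .data$site_id, direction = "exit",
                     timestamp = .data$t_out)
  )
  ev[order_stable(ev$timestamp), ]
}

#' Generate a synthetic antenna event log
#'
#' Convenience wrapper: simulates ground-truth trajectories
#' ([generate_stays()]) and serialises them as a directional event log
#' ([stays_to_events()]).
#'
#' @inheritParams generate_stays
#' @return Event tibble sorted by timestamp.
#' @export
generate_event_log <- function(truth, seed = truth$seed + 1000) {
  stays_to_events(generate_stays(truth, seed = seed))
}
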