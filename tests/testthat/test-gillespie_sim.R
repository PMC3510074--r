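# small 3-box model with distinct, hand-set rates
toy_model <- function() {
  boxes <- c("B1", "B2", "B3")
  leave <- matrix(c(
    1e-3, 2e-3, 1e-3,
    5e-4, 1e-3, 2e-3,
    1e-3, 1e-3, 5e-4
  ), 3, 3, byrow = TRUE)
  transit <- matrix(1 / 120, 3, 3)
  rate_model(boxes, leave, transit)
}

test_that("rate estimation matches hand-worked example and normalisation", {
  # two stays in B1 of 10 s and 20 s, both departing to B2:
  # total leave rate 2 / 30 = 1/15; all of it towards B2
  stays <- tibble::tibble(animal_id = "a", site_id = c("B1", "B2", "B1", "B2"),
                          t_in = c(0, 20, 100, 140), t_out = c(10, 30, 120, 150))
  transits <- stays_to_transits(stays)
  m <- estimate_rates(stays, transits)
  expect_equal(m$leave["B1", "B2"], 1 / 15)
  expect_equal(sum(m$leave["B1", ]), 1 / 15)
  expect_equal(m$transit["B1", "B2"], 1 / mean(c(10, 20)))

  mn <- estimate_rates(stays, transits, paper_normalise = TRUE)
  expect_equal(sum(mn$leave), 1)
  expect_equal(sum(mn$transit), 1)
  # normalisation only rescales: ratios preserved
  expect_equal(mn$leave / sum(mn$leave) * sum(m$leave), m$leave)

  # a box with no departures is an error
  stays2 <- tibble::tibble(animal_id = "a", site_id = c("B1", "B9"),
                           t_in = c(0, 20), t_out = c(10, 40))
  expect_error(estimate_rates(stays2, stays_to_transits(stays2)),
               "no observed departures")
})

test_that("rates recovered from synthetic data approach generator truth", {
  set.seed(44)
  truth <- generate_colony(n_sites = 3, n_animals = 10, duration = 1.2e6,
                           n_clusters = 1, transit_scale = 30,
                           transit_sdlog = 0.8, seed = 44)
  stays <- generate_stays(truth)
  m <- estimate_rates(stays, stays_to_transits(stays))
  rel <- abs(m$leave / truth$rates$leave - 1)
  expect_lt(median(rel), 0.1)
  rel_t <- abs(m$transit / truth$rates$transit - 1)
  expect_lt(median(rel_t), 0.1)
})

test_that("waiting times and agent selection follow the Gillespie law", {
  model <- toy_model()
  n <- length(model$boxes)

  # one agent in B1: empirical mean waiting time = 1 / total rate within 1%
  set.seed(51)
  st <- list(agent_state = 1L, t = 0)
  omega <- sum(model$leave[1, ])
  dts <- vapply(seq_len(1e5), function(i) gillespie_step(st, model)$dt,
                numeric(1))
  expect_lt(abs(mean(dts) * omega - 1), 0.01)

  # degenerate selection: an agent with zero rate is never chosen
  model0 <- model
  st2 <- list(agent_state = c(1L, n + 0L * n + 2L), t = 0)  # B1 + transit B1->B2
  m0 <- model
  m0$transit[1, 2] <- 0  # agent 2 now carries zero rate
  picks <- vapply(seq_len(1e4), function(i) gillespie_step(st2, m0)$agent,
                  integer(1))
  expect_true(all(picks == 1L))

  # selection frequencies match omega_k / sum(omega) (chi-square)
  set.seed(52)
  st3 <- list(agent_state = c(1L, 2L, 3L), t = 0)
  omegas <- rowSums(model$leave)
  picks <- vapply(seq_len(1e5), function(i) gillespie_step(st3, model)$agent,
                  integer(1))
  obs <- tabulate(picks, 3)
  p <- stats::chisq.test(obs, p = omegas / sum(omegas))$p.value
  expect_gt(p, 0.01)
})

test_that("destination choice is equivalent to the competing-rates race", {
  # transitions out of each box occur towards j with frequency
  # leave[i, j] / total_leave[i]
  set.seed(53)
  model <- toy_model()
  sim <- simulate_colony(model, n_agents = 10, duration = 4e5, seed = 53)
  tr <- stays_to_transits(sim$stays)
  for (i in seq_len(3)) {
    cnt <- table(factor(tr$to_site[tr$from_site == model$boxes[i]],
                        levels = model$boxes))
    p <- stats::chisq.test(as.vector(cnt),
                           p = model$leave[i, ] / sum(model$leave[i, ]))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("simulation conserves agents and reproduces with a seed", {
  model <- toy_model()
  sim1 <- simulate_colony(model, n_agents = 5, duration = 1e5, seed = 99)
  sim2 <- simulate_colony(model, n_agents = 5, duration = 1e5, seed = 99)
  expect_identical(sim1$stays, sim2$stays)
  expect_equal(dplyr::n_distinct(sim1$stays$animal_id), 5)

  # a single agent can never meet anyone
  sim_solo <- simulate_colony(model, n_agents = 1, duration = 2e5, seed = 7)
  expect_equal(nrow(sim_solo$encounters), 0)

  # stays never overlap per agent (agent is in one place at a time)
  expect_silent(stays_to_transits(sim1$stays))
  expect_error(simulate_colony(model, 2, -5), "duration")
})

test_that("inter-event times in a box are exponential at the total leave rate", {
  set.seed(61)
  model <- toy_model()
  sim <- simulate_colony(model, n_agents = 8, duration = 1e6, seed = 61)
  st <- sim$stays
  durations <- (st$t_out - st$t_in)[st$site_id == "B1"]
  # drop stays truncated by the window end
  durations <- durations[st$t_out[st$site_id == "B1"] < 1e6]
  expect_gt(length(durations), 1e3)
  rate <- sum(model$leave[1, ])
  ks <- stats::ks.test(durations, "pexp", rate)
  expect_gt(ks$p.value, 0.01)
})

test_that("rates estimated from simulation output converge to the input model", {
  set.seed(71)
  model <- toy_model()
  sim <- simulate_colony(model, n_agents = 12, duration = 2e6, seed = 71)
  m_hat <- estimate_rates(sim$stays, stays_to_transits(sim$stays))
  expect_equal(m_hat$boxes, model$boxes)
  expect_lt(max(abs(m_hat$leave / model$leave - 1)), 0.15)
  expect_lt(max(abs(m_hat$transit / model$transit - 1)), 0.15)
})

test_that("metric suite counts what it says it counts", {
  # one animal, 3 stays in 2 boxes within one day
  st <- tibble::tibble(animal_id = "a", site_id = c("B1", "B2", "B1"),
                       t_in = c(0, 3600, 7200), t_out = c(100, 3700, 7300))
  ms <- compute_metrics(st, extract_encounters(st))
  d <- ms$distributions
  expect_equal(d$value[d$metric == "stays_per_day"], 3)
  expect_equal(d$value[d$metric == "boxes_per_day"], 2)
  expect_equal(d$value[d$metric == "encounters_per_day"], 0)

  # encounter rate: 10 encounters, 20 stays, mean stay 100 s -> 0.005 / s
  st2 <- tibble::tibble(animal_id = rep(c("a", "b"), each = 10),
                        site_id = "B1",
                        t_in = rep(seq(0, 9) * 1000, 2),
                        t_out = rep(seq(0, 9) * 1000, 2) + 100)
  en2 <- extract_encounters(st2)
  expect_equal(nrow(en2), 10)
  ms2 <- compute_metrics(st2, en2)
  expect_equal(ms2$scalars$value[ms2$scalars$metric == "encounter_rate"],
               (10 / 20) / 100)
  expect_equal(ms2$scalars$value[ms2$scalars$metric == "mean_agents_per_day"], 2)
  # partners never exceed encounters per individual-day
  expect_true(all(ms2$per_day$partners <= ms2$per_day$encounters))

  # metrics survive a CSV round trip of their inputs
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_stay_table(st2, f1)
  ms3 <- compute_metrics(read_stay_table(f1), en2)
  expect_equal(ms3$distributions, ms2$distributions)
  expect_equal(ms3$scalars, ms2$scalars)
})

test_that("tidiers expose rate models and metric sets as tibbles", {
  model <- toy_model()
  td <- tidy(model)
  expect_equal(nrow(td), 9)
  expect_equal(td$leave_rate[td$from == "B1" & td$to == "B2"],
               model$leave["B1", "B2"])
  expect_equal(glance(model)$n_boxes, 3)

  st <- tibble::tibble(animal_id = "a", site_id = "B1", t_in = 0, t_out = 10)
  ms <- compute_metrics(st, extract_encounters(st))
  expect_true(all(c("metric", "value") %in% names(tidy(ms))))
  expect_true("encounter_rate" %in% names(glance(ms)))
})
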