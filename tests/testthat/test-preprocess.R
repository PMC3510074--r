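test_that("enter/exit pairing recovers stays, with policy control", {
  ev <- tibble::tibble(
    animal_id = c("a", "a"), site_id = c("B1", "B1"),
    direction = c("enter", "exit"), timestamp = c(0, 10)
  )
  st <- events_to_stays(ev)
  expect_equal(st$t_out - st$t_in, 10)

  # missing implicit exit: strict errors, default drops the dangling enter
  ev2 <- tibble::tibble(
    animal_id = c("a", "a"), site_id = c("B1", "B2"),
    direction = c("enter", "enter"), timestamp = c(0, 5)
  )
  expect_error(events_to_stays(ev2, policy = "strict"), "implicit exit")
  expect_silent(suppressMessages(st2 <- events_to_stays(ev2)))
  expect_equal(nrow(st2), 0)

  # exit with no pending enter
  ev3 <- tibble::tibble(animal_id = "a", site_id = "B1",
                        direction = "exit", timestamp = 3)
  expect_error(events_to_stays(ev3, policy = "strict"), "no matching enter")

  # generator inversion: a serialised stay table is recovered exactly
  set.seed(7)
  truth <- generate_colony(n_sites = 5, n_animals = 6, duration = 2e5, seed = 7)
  stays <- generate_stays(truth)
  rec <- events_to_stays(stays_to_events(stays))
  expect_equal(as.data.frame(rec),
               as.data.frame(dplyr::arrange(stays, animal_id, t_in)))
})

test_that("transits link consecutive stays and keep self-returns", {
  st <- tibble::tibble(animal_id = "a", site_id = c("B1", "B2"),
                       t_in = c(0, 20), t_out = c(10, 30))
  tr <- stays_to_transits(st)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$from_site, "B1")
  expect_equal(tr$to_site, "B2")
  expect_equal(tr$duration, 10)

  st2 <- tibble::tibble(animal_id = "a", site_id = c("B1", "B1"),
                        t_in = c(0, 15), t_out = c(10, 30))
  tr2 <- stays_to_transits(st2)
  expect_equal(tr2$to_site, "B1")
  expect_equal(tr2$duration, 5)

  # combinatorial identity: per animal, transits = stays - 1
  st3 <- tiny_stays()
  tr3 <- stays_to_transits(st3)
  expect_equal(nrow(tr3), nrow(st3) - dplyr::n_distinct(st3$animal_id))

  over <- tibble::tibble(animal_id = "a", site_id = c("B1", "B2"),
                         t_in = c(0, 5), t_out = c(10, 20))
  expect_error(stays_to_transits(over), "Overlapping stays for animal a")
})

test_that("encounters are pairwise stay overlaps with half-open intervals", {
  st <- tibble::tibble(animal_id = c("a", "b"), site_id = "B1",
                       t_in = c(0, 5), t_out = c(10, 15))
  en <- extract_encounters(st)
  expect_equal(nrow(en), 1)
  expect_equal(en$duration, 5)
  expect_equal(c(en$animal_a, en$animal_b), c("a", "b"))

  # touching stays do not meet
  st2 <- tibble::tibble(animal_id = c("a", "b"), site_id = "B1",
                        t_in = c(0, 5), t_out = c(5, 10))
  expect_equal(nrow(extract_encounters(st2)), 0)

  # k co-resident animals -> k(k-1)/2 dyads
  st3 <- tibble::tibble(animal_id = c("a", "b", "c"), site_id = "B1",
                        t_in = 0, t_out = 10)
  expect_equal(nrow(extract_encounters(st3)), 3)

  # different sites never meet
  st4 <- tibble::tibble(animal_id = c("a", "b"), site_id = c("B1", "B2"),
                        t_in = 0, t_out = 10)
  expect_equal(nrow(extract_encounters(st4)), 0)

  expect_equal(nrow(extract_encounters(st[0, ])), 0)
})

test_that("encounter extraction is symmetric and order-invariant", {
  set.seed(31)
  truth <- generate_colony(n_sites = 3, n_animals = 8, duration = 4e4, seed = 31)
  stays <- generate_stays(truth)
  en1 <- extract_encounters(stays)
  en2 <- extract_encounters(stays[sample.int(nrow(stays)), ])
  expect_equal(as.data.frame(en1), as.data.frame(en2))
  expect_true(all(en1$animal_a < en1$animal_b))
  expect_true(all(en1$duration > 0))
})

test_that("bridge summary pools directions, filters, and uses medians", {
  lay <- tiny_layout(3)
  tr <- tibble::tibble(
    animal_id = "a",
    from_site = c("B1", "B2", "B1"), to_site = c("B2", "B1", "B2"),
    t_start = 0, t_end = 1,
    duration = c(1, 2, 100)
  )
  bs <- bridge_summary(tr, lay, min_crossings = 1)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$n_cross, 3L)
  expect_equal(bs$median_duration, 2)  # heavy tail does not drag the median
  expect_equal(bs$distance, 2)

  # a pair one crossing short of the threshold is excluded
  tr49 <- tibble::tibble(animal_id = "a", from_site = "B1", to_site = "B2",
                         t_start = 0, t_end = 1, duration = rep(10, 49))
  expect_equal(nrow(bridge_summary(tr49, lay, min_crossings = 50)), 0)
  expect_equal(nrow(bridge_summary(tr49, lay, min_crossings = 49)), 1)

  # self-transits carry no bridge
  tr_self <- tibble::tibble(animal_id = "a", from_site = "B1", to_site = "B1",
                            t_start = 0, t_end = 1, duration = rep(5, 100))
  expect_equal(nrow(bridge_summary(tr_self, lay, min_crossings = 1)), 0)

  expect_error(
    bridge_summary(dplyr::mutate(tr, to_site = "NOPE"), lay, 1),
    "not in the layout"
  )

  # order invariance
  set.seed(13)
  truth <- generate_colony(n_sites = 4, n_animals = 6, duration = 2e5, seed = 13)
  trs <- stays_to_transits(generate_stays(truth))
  b1 <- bridge_summary(trs, truth$layout, min_crossings = 10)
  b2 <- bridge_summary(trs[sample.int(nrow(trs)), ], truth$layout,
                       min_crossings = 10)
  expect_equal(as.data.frame(b1), as.data.frame(b2))
})

test_that("bridge summary medians recover generator truth", {
  set.seed(17)
  truth <- generate_colony(n_sites = 3, n_animals = 10, duration = 2e6,
                           n_clusters = 1, transit_sdlog = 1.0, seed = 17)
  trs <- stays_to_transits(generate_stays(truth))
  bs <- bridge_summary(trs, truth$layout, min_crossings = 200)
  expect_gt(nrow(bs), 0)
  for (k in seq_len(nrow(bs))) {
    i <- match(bs$site_a[k], truth$layout$site_id)
    j <- match(bs$site_b[k], truth$layout$site_id)
    true_med <- exp(truth$transit_meanlog[i, j])  # lognormal median
    expect_lt(abs(bs$median_duration[k] / true_med - 1), 0.10)
  }
})

test_that("effective speed calibration takes the fastest bridge", {
  b <- tibble::tibble(site_a = c("B1", "B1"), site_b = c("B2", "B3"),
                      n_cross = c(10L, 10L), distance = c(2, 1),
                      median_duration = c(100, 200))
  expect_equal(calibrate_vbar(b), 0.02)

  # single bridge: its own drift speed, and D = 0 by construction
  b1 <- b[1, ]
  v <- calibrate_vbar(b1)
  expect_equal(bridge_diffusion(b1$distance, b1$median_duration, v), 0)

  # argmax bridge gets D = 0, all others D > 0; adding a faster bridge
  # never lowers vbar
  set.seed(41)
  for (rep in 1:5) {
    n <- 6
    bb <- tibble::tibble(site_a = "x", site_b = letters[1:n],
                         n_cross = 5L, distance = runif(n, 0.5, 5),
                         median_duration = runif(n, 50, 500))
    v <- calibrate_vbar(bb)
    D <- bridge_diffusion(bb$distance, bb$median_duration, v)
    expect_equal(min(D), 0)
    expect_equal(sum(D == 0), 1)
    bb2 <- dplyr::bind_rows(bb, tibble::tibble(
      site_a = "x", site_b = "z", n_cross = 5L,
      distance = 5, median_duration = 5 / (2 * v)))
    expect_gte(calibrate_vbar(bb2), v)
  }

  expect_error(calibrate_vbar(tibble::tibble(distance = 0,
                                             median_duration = 10,
                                             n_cross = 1L)),
               "degenerate")
})
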