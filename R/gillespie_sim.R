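#' Rate model for the multi-agent null simulation
#'
#' The "average mouse" null model lives on `n` box states plus up to `n^2`
#' directed transit states. `leave[i, j]` is the rate (1/s) at which an
#' agent sitting in box `i` departs towards box `j` (the diagonal holds
#' exit-and-return self-loops); the total leave rate of box `i` is the row
#' sum, and destinations are chosen in proportion to the row. `transit[i,
#' j]` is the rate at which a transit from `i` to `j` completes (the agent
#' enters `j`).
#'
#' @param boxes Character vector of box identifiers.
#' @param leave,transit `n x n` non-negative rate matrices (1/s).
#' @param normalised Logical flag recording whether the matrices were
#'   rescaled to sum to one (a pure change of time unit).
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(boxes, leave, transit, normalised = FALSE) {
  n <- length(boxes)
  if (!is.matrix(leave) || !all(dim(leave) == n) ||
      !is.matrix(transit) || !all(dim(transit) == n)) {
    abort("`leave` and `transit` must be n x n matrices matching `boxes`.")
  }
  if (any(leave < 0) || any(transit < 0)) abort("Rates must be >= 0.")
  if (any(rowSums(leave) <= 0)) {
    abort(sprintf("Box(es) %s have zero total leave rate.",
                  paste(boxes[rowSums(leave) <= 0], collapse = ", ")))
  }
  if (any(leave > 0 & transit <= 0)) {
    bad <- which(leave > 0 & transit <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Transit %s->%s is reachable (leave rate > 0) but has no completion rate.",
                  boxes[bad[1]], boxes[bad[2]]))
  }
  dimnames(leave) <- dimnames(transit) <- list(boxes, boxes)
  structure(list(boxes = boxes, leave = leave, transit = transit,
                 normalised = normalised),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %d boxes%s\n", length(x$boxes),
              if (x$normalised) " (normalised rates)" else ""))
  cat(sprintf("  total leave rates: %.3g-%.3g 1/s; %d active transit states\n",
              min(rowSums(x$leave)), max(rowSums(x$leave)), sum(x$leave > 0)))
  invisible(x)
}

#' Estimate box and transit rates from data
#'
#' Fits the null model's competing-exponential rates to observed stays and
#' transits. The departure rate towards each destination is the
#' competing-risks estimate
#' `leave[i, j] = (departures i -> j) / (total stay time in box i)`
#' (so the total leave rate of a box is the inverse of its mean stay
#' duration and destinations are chosen with their empirical frequencies),
#' and `transit[i, j]` is the inverse of the mean transit duration from
#' `i` to `j`. With `paper_normalise = TRUE` both matrices are rescaled to
#' sum to 1, a pure change of time unit that leaves all occupancy ratios
#' untouched; the default keeps physical rates so simulated durations stay
#' in seconds.
#'
#' @param stays Stay table.
#' @param transits Transit table from [stays_to_transits()] (must derive
#'   from the same stays).
#' @param paper_normalise Rescale each matrix to sum 1 (default `FALSE`).
#' @return A [rate_model()].
#' @export
estimate_rates <- function(stays, transits, paper_normalise = FALSE) {
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"))
  assert_columns(transits, c("animal_id", "from_site", "to_site",
                             "t_start", "duration"))
  boxes <- sort(unique(c(stays$site_id, transits$from_site, transits$to_site)))
  n <- length(boxes)
  # stays that end in an observed departure, keyed by (box, destination)
  stays_k <- dplyr::arrange(stays, .data$animal_id, .data$t_in)
  dep <- stays_k |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(to_site = dplyr::lead(.data$site_id)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to_site))
  no_dep <- setdiff(boxes, unique(dep$site_id))
  if (length(no_dep) > 0) {
    abort(sprintf("Box(es) %s have no observed departures; cannot estimate leave rates.",
                  paste(no_dep, collapse = ", ")))
  }
  time_in_box <- dep |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(total = sum(.data$t_out - .data$t_in), .groups = "drop")
  counts <- dep |>
    dplyr::count(.data$site_id, .data$to_site)
  leave <- matrix(0, n, n, dimnames = list(boxes, boxes))
  tot <- setNames(time_in_box$total, time_in_box$site_id)
  leave[cbind(match(counts$site_id, boxes), match(counts$to_site, boxes))] <-
    counts$n / tot[counts$site_id]
  tmean <- transits |>
    dplyr::group_by(.data$from_site, .data$to_site) |>
    dplyr::summarise(m = mean(.data$duration), .groups = "drop")
  transit <- matrix(0, n, n, dimnames = list(boxes, boxes))
  transit[cbind(match(tmean$from_site, boxes), match(tmean$to_site, boxes))] <-
    1 / tmean$m
  if (any(leave > 0 & transit <= 0)) {
    # a departure was observed whose transit never completed in-window;
    # treat the pair mean over all observed transits as authoritative
    leave[leave > 0 & transit <= 0] <- 0
  }
  if (paper_normalise) {
    leave <- leave / sum(leave)
    transit <- transit / sum(transit)
  }
  rate_model(boxes, leave, transit, normalised = paper_normalise)
}

# ---- Gillespie machinery --------------------------------------------------

# Agent states are encoded as integers: 1..n = inside box i,
# n + (i-1)*n + j = in transit from i to j.
state_rate <- function(state, model) {
  n <- length(model$boxes)
  total_leave <- rowSums(model$leave)
  ifelse(state <= n, total_leave[state],
         model$transit[cbind((state - n - 1L) %/% n + 1L,
                             (state - n - 1L) %% n + 1L)])
}

#' One Gillespie step
#'
#' Advances a system of agents by a single stochastic event: the waiting
#' time is exponential with mean `1 / sum(omega)` over the agents' current
#' transition rates, the acting agent is chosen with probability
#' proportional to its rate by mapping one uniform draw onto the cumulative
#' rates (ties broken by agent index), and the agent's state is updated
#' (box -> transit with destination chosen proportionally to the departure
#' rates; transit -> destination box).
#'
#' @param state A list with elements `agent_state` (integer encoding: `i`
#'   for box `i`, `n + (i-1)*n + j` for transit `i -> j`), `t` (clock,
#'   seconds).
#' @param model A [rate_model()].
#' @return The updated state list, with extra elements `dt` (the waiting
#'   time just sampled) and `agent` (who moved).
#' @export
gillespie_step <- function(state, model) {
  n <- length(model$boxes)
  omega <- state_rate(state$agent_state, model)
  total <- sum(omega)
  if (total <= 0) abort("All transition rates are zero: absorbing system.")
  dt <- rexp(1, rate = total)
  k <- findInterval(runif(1) * total, cumsum(omega), left.open = TRUE) + 1L
  k <- min(k, length(omega))
  s <- state$agent_state[k]
  if (s <= n) {
    rates <- model$leave[s, ]
    j <- findInterval(runif(1) * sum(rates), cumsum(rates), left.open = TRUE) + 1L
    j <- min(j, n)
    new_s <- n + (s - 1L) * n + j
  } else {
    new_s <- (s - n - 1L) %% n + 1L
  }
  state$agent_state[k] <- as.integer(new_s)
  state$t <- state$t + dt
  state$dt <- dt
  state$agent <- k
  state
}

#' Simulate the multi-agent null model
#'
#' Runs `n_agents` identical, non-interacting agents over the box/transit
#' state space for `duration` seconds with the Gillespie algorithm, and
#' emits the resulting stays and pairwise encounters in exactly the schema
#' of observed data, so every downstream computation (metrics, rates,
#' landscapes) is shared between real and simulated records. Agents are
#' initialised by sampling states from `init` (default: the stationary
#' distribution of the model's Markov chain, mirroring initialisation by
#' observed occupancy preferences; if the chain is reducible, agents start
#' in boxes with probability proportional to expected residence time).
#'
#' @param model A [rate_model()].
#' @param n_agents Number of agents (constant through the run).
#' @param duration Simulated time span, seconds.
#' @param init Optional probability vector over the full state space
#'   (boxes then transit states, see [build_generator()] for the
#'   enumeration) used to draw initial agent states.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `stays` and `encounters` tibbles; agent identifiers
#'   are `"sim_001"`, ... Stays open at the end of the run are closed at
#'   `duration`.
#' @export
simulate_colony <- function(model, n_agents, duration, init = NULL,
                            seed = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (n_agents < 1) abort("`n_agents` must be >= 1.")
  assert_scalar_number(duration, "duration", positive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(model$boxes)
  total_leave <- rowSums(model$leave)
  cum_leave <- apply(model$leave, 1, cumsum)  # n x n, column i = cumsum of row i

  g <- tryCatch(build_generator(model), error = function(e) NULL)
  if (is.null(g)) {
    # reducible chain (e.g. strictly territorial data): start agents in
    # boxes with probability proportional to expected residence
    states_enc <- seq_len(n)
    probs <- (1 / total_leave) / sum(1 / total_leave)
    if (!is.null(init)) {
      abort("`init` needs the full state space, but the model's chain is reducible.")
    }
  } else if (is.null(init)) {
    states_enc <- g$state_code
    probs <- stationary_distribution(g$Q)
  } else {
    if (length(init) != length(g$state_code) || any(init < 0)) {
      abort("`init` must be a non-negative vector over the model's state space.")
    }
    states_enc <- g$state_code
    probs <- init / sum(init)
  }
  ids <- sprintf("sim_%03d", seq_len(n_agents))
  agent_state <- states_enc[sample.int(length(states_enc), n_agents,
                                       replace = TRUE, prob = probs)]
  omega <- state_rate(agent_state, model)

  # stay recording
  cap <- 4096L
  st_agent <- integer(cap); st_box <- integer(cap)
  st_in <- numeric(cap); st_out <- numeric(cap); n_st <- 0L
  open_t <- rep(NA_real_, n_agents)
  in_box <- agent_state <= n
  open_t[in_box] <- 0
  push_stay <- function(a, b, t0, t1) {
    n_st <<- n_st + 1L
    if (n_st > cap) {
      cap <<- cap * 2L
      length(st_agent) <<- cap; length(st_box) <<- cap
      length(st_in) <<- cap; length(st_out) <<- cap
    }
    st_agent[n_st] <<- a; st_box[n_st] <<- b
    st_in[n_st] <<- t0; st_out[n_st] <<- t1
  }

  t <- 0
  repeat {
    total <- sum(omega)
    if (total <= 0) abort("All transition rates are zero: absorbing system.")
    dt <- rexp(1, rate = total)
    if (t + dt > duration) break
    t <- t + dt
    k <- findInterval(runif(1) * total, cumsum(omega), left.open = TRUE) + 1L
    k <- min(k, n_agents)
    s <- agent_state[k]
    if (s <= n) {
      # leave box s towards j
      j <- findInterval(runif(1) * total_leave[s], cum_leave[, s],
                        left.open = TRUE) + 1L
      j <- min(j, n)
      if (t > open_t[k]) push_stay(k, s, open_t[k], t)
      open_t[k] <- NA_real_
      agent_state[k] <- n + (s - 1L) * n + j
      omega[k] <- model$transit[s, j]
    } else {
      j <- (s - n - 1L) %% n + 1L
      agent_state[k] <- j
      open_t[k] <- t
      omega[k] <- total_leave[j]
    }
  }
  open <- which(!is.na(open_t) & open_t < duration)
  for (k in open) push_stay(k, agent_state[k], open_t[k], duration)

  stays <- tibble(
    animal_id = ids[st_agent[seq_len(n_st)]],
    site_id = model$boxes[st_box[seq_len(n_st)]],
    t_in = st_in[seq_len(n_st)],
    t_out = st_out[seq_len(n_st)]
  ) |> dplyr::arrange(.data$animal_id, .data$t_in)
  list(stays = stays, encounters = extract_encounters(stays))
}

# ---- metrics --------------------------------------------------------------

#' Behavioural metric suite
#'
#' Computes the per-individual metric distributions used to compare
#' observed and simulated behaviour: per individual-day counts of stays,
#' distinct boxes visited, encounters and distinct social partners, plus
#' the pooled distributions of stay and encounter durations; and two
#' system-level scalars, the mean number of individuals detected per day
#' and the global encounter rate
#' `(encounters / stays) / mean stay duration` (1/s).
#'
#' Days are calendar windows of `day_length` seconds counted from `t0`;
#' an individual contributes a given day only if it has at least one stay
#' starting that day (encounters are assigned to days by their start, to
#' each member of the pair).
#'
#' @param stays Stay table.
#' @param encounters Encounter table ([extract_encounters()]).
#' @param t0 Origin of the day grid, seconds (default 0).
#' @param day_length Day length, seconds (default 86400).
#' @return An object of class `metric_set`: list with `distributions`
#'   (long tibble `metric`, `value`), `per_day` (tibble of per
#'   individual-day counts) and `scalars` (tibble `metric`, `value`).
#' @export
compute_metrics <- function(stays, encounters, t0 = 0, day_length = 86400) {
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"))
  assert_columns(encounters, c("animal_a", "animal_b", "t_start", "duration"))
  if (nrow(stays) == 0) {
    empty <- tibble(metric = character(), value = double())
    return(structure(list(distributions = empty,
                          per_day = tibble(animal_id = character(),
                                           day = integer(), stays = integer(),
                                           boxes = integer(), encounters = integer(),
                                           partners = integer()),
                          scalars = empty),
                     class = "metric_set"))
  }
  sd_tbl <- stays |>
    dplyr::mutate(day = new_day_index(.data$t_in, t0, day_length)) |>
    dplyr::group_by(.data$animal_id, .data$day) |>
    dplyr::summarise(stays = dplyr::n(),
                     boxes = dplyr::n_distinct(.data$site_id),
                     .groups = "drop")
  enc_long <- dplyr::bind_rows(
    dplyr::transmute(encounters, animal_id = .data$animal_a,
                     partner = .data$animal_b, t_start = .data$t_start),
    dplyr::transmute(encounters, animal_id = .data$animal_b,
                     partner = .data$animal_a, t_start = .data$t_start)
  ) |>
    dplyr::mutate(day = new_day_index(.data$t_start, t0, day_length)) |>
    dplyr::group_by(.data$animal_id, .data$day) |>
    dplyr::summarise(encounters = dplyr::n(),
                     partners = dplyr::n_distinct(.data$partner),
                     .groups = "drop")
  per_day <- dplyr::left_join(sd_tbl, enc_long, by = c("animal_id", "day")) |>
    dplyr::mutate(encounters = dplyr::coalesce(.data$encounters, 0L),
                  partners = dplyr::coalesce(.data$partners, 0L))
  distributions <- dplyr::bind_rows(
    tibble(metric = "stays_per_day", value = as.double(per_day$stays)),
    tibble(metric = "boxes_per_day", value = as.double(per_day$boxes)),
    tibble(metric = "encounters_per_day", value = as.double(per_day$encounters)),
    tibble(metric = "partners_per_day", value = as.double(per_day$partners)),
    tibble(metric = "stay_duration", value = stays$t_out - stays$t_in),
    tibble(metric = "encounter_duration", value = encounters$duration)
  )
  mean_stay <- mean(stays$t_out - stays$t_in)
  scalars <- tibble(
    metric = c("mean_agents_per_day", "encounter_rate"),
    value = c(
      mean(dplyr::count(dplyr::distinct(
        dplyr::mutate(stays, day = new_day_index(.data$t_in, t0, day_length)),
        .data$animal_id, .data$day), .data$day)$n),
      (nrow(encounters) / nrow(stays)) / mean_stay
    )
  )
  structure(list(distributions = distributions, per_day = per_day,
                 scalars = scalars),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  s <- x$distributions |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  print(as.data.frame(s), row.names = FALSE)
  print(as.data.frame(x$scalars), row.names = FALSE)
  invisible(x)
}

#' Per-box occupancy fractions and transit counts
#'
#' `box_occupancy()` returns, for each box, the fraction of total recorded
#' animal-time spent in it; `transit_counts()` tallies directed transit
#' counts. Both are the aggregate vectors used to check a simulation
#' against the data that calibrated it.
#'
#' @param stays Stay table.
#' @param boxes Optional box universe (character); defaults to the boxes
#'   present.
#' @return A tibble `site_id`, `time_fraction`, `n_stays`.
#' @export
box_occupancy <- function(stays, boxes = NULL) {
  assert_columns(stays, c("site_id", "t_in", "t_out"))
  occ <- stays |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(total = sum(.data$t_out - .data$t_in),
                     n_stays = dplyr::n(), .groups = "drop")
  if (!is.null(boxes)) {
    occ <- dplyr::left_join(tibble(site_id = boxes), occ, by = "site_id") |>
      dplyr::mutate(total = dplyr::coalesce(.data$total, 0),
                    n_stays = dplyr::coalesce(.data$n_stays, 0L))
  }
  occ$time_fraction <- occ$total / sum(occ$total)
  occ[, c("site_id", "time_fraction", "n_stays")]
}

#' @rdname box_occupancy
#' @param transits Transit table.
#' @return For `transit_counts()`: a tibble `from_site`, `to_site`, `n`.
#' @export
transit_counts <- function(transits, boxes = NULL) {
  assert_columns(transits, c("from_site", "to_site"))
  ct <- dplyr::count(transits, .data$from_site, .data$to_site)
  if (!is.null(boxes)) {
    full <- tidyr::expand_grid(from_site = boxes, to_site = boxes)
    ct <- dplyr::left_join(full, ct, by = c("from_site", "to_site")) |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  ct
}
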