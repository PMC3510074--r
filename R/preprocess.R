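#' Pair directional antenna events into stays
#'
#' Walks each animal's event stream chronologically and pairs every `enter`
#' with the next `exit` of the same animal at the same site. An animal is
#' assumed to be in at most one site at a time, so an `enter` while a stay
#' is already open, or an `exit` with no open stay, is an unmatched event:
#' under the default `"drop"` policy unmatched events are discarded (with a
#' message reporting how many); under `"strict"` they are an error.
#'
#' @param events Tibble of events as returned by [read_event_log()], sorted
#'   by timestamp.
#' @param min_stay Minimum stay duration in seconds; shorter stays are
#'   discarded (default 0, i.e. no filter).
#' @param policy `"drop"` (default) or `"strict"` handling of unmatched
#'   events.
#' @return A stay table: tibble with `animal_id`, `site_id`, `t_in`,
#'   `t_out`.
#' @export
events_to_stays <- function(events, min_stay = 0, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  assert_columns(events, c("animal_id", "site_id", "direction", "timestamp"))
  assert_scalar_number(min_stay, "min_stay", nonneg = TRUE)
  if (nrow(events) == 0) {
    return(tibble(animal_id = character(), site_id = character(),
                  t_in = double(), t_out = double()))
  }
  if (is.unsorted(events$timestamp)) {
    abort("`events` must be sorted by timestamp (see read_event_log()).")
  }
  out <- vector("list", length(unique(events$animal_id)))
  dropped <- 0L
  idx <- 0L
  for (ev in split(events, events$animal_id)) {
    idx <- idx + 1L
    open_site <- NA_character_
    open_t <- NA_real_
    t_in <- numeric(0); t_out <- numeric(0); site <- character(0)
    for (k in seq_len(nrow(ev))) {
      d <- ev$direction[k]
      if (d == "enter") {
        if (!is.na(open_site)) {
          if (policy == "strict") {
            abort(sprintf("Animal %s enters %s at t=%g while a stay at %s is open (implicit exit missing).",
                          ev$animal_id[k], ev$site_id[k], ev$timestamp[k], open_site))
          }
          dropped <- dropped + 1L  # discard the dangling enter
        }
        open_site <- ev$site_id[k]
        open_t <- ev$timestamp[k]
      } else {
        if (is.na(open_site) || open_site != ev$site_id[k]) {
          if (policy == "strict") {
            abort(sprintf("Animal %s exits %s at t=%g with no matching enter.",
                          ev$animal_id[k], ev$site_id[k], ev$timestamp[k]))
          }
          dropped <- dropped + 1L
          next
        }
        site <- c(site, open_site); t_in <- c(t_in, open_t)
        t_out <- c(t_out, ev$timestamp[k])
        open_site <- NA_character_; open_t <- NA_real_
      }
    }
    if (!is.na(open_site)) dropped <- dropped + 1L
    out[[idx]] <- tibble(animal_id = rep(ev$animal_id[1], length(site)),
                         site_id = site, t_in = t_in, t_out = t_out)
  }
  stays <- dplyr::bind_rows(out)
  if (dropped > 0) inform(sprintf("events_to_stays: dropped %d unmatched event(s).", dropped))
  stays <- stays[stays$t_out - stays$t_in >= pmax(min_stay, .Machine$double.xmin), ]
  stays <- stays[stays$t_out > stays$t_in, ]
  dplyr::arrange(stays, .data$animal_id, .data$t_in)
}

#' Derive transits from a stay table
#'
#' Every pair of consecutive stays of the same animal defines one transit
#' from the first stay's site to the second's, lasting from the first exit
#' to the next entry. Returns to the same site (self-transits) are retained:
#' they carry rate information even though they span no distance.
#'
#' @param stays A stay table (see [events_to_stays()]).
#' @return Tibble with `animal_id`, `from_site`, `to_site`, `t_start`,
#'   `t_end`, `duration` (seconds).
#' @export
stays_to_transits <- function(stays) {
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"))
  validate_stays(stays)
  stays <- dplyr::arrange(stays, .data$animal_id, .data$t_in)
  tr <- stays |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      to_site = dplyr::lead(.data$site_id),
      t_end = dplyr::lead(.data$t_in)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to_site)) |>
    dplyr::transmute(
      animal_id = .data$animal_id,
      from_site = .data$site_id,
      to_site = .data$to_site,
      t_start = .data$t_out,
      t_end = .data$t_end,
      duration = .data$t_end - .data$t_out
    )
  bad <- which(tr$duration <= 0)
  if (length(bad) > 0) {
    b <- tr[bad[1], ]
    abort(sprintf("Overlapping stays for animal %s around [%g, %g]: stays of one animal must not overlap.",
                  b$animal_id, b$t_start, b$t_end))
  }
  tr
}

#' Extract pairwise encounters from overlapping stays
#'
#' Two animals meet when their stays in the same site overlap; each
#' overlapping pair of stays yields one encounter whose duration is the
#' length of the overlap (intervals are half-open, so stays that merely
#' touch do not count). If k animals are co-resident, all k(k-1)/2 dyads
#' are counted.
#'
#' @param stays A stay table.
#' @return Tibble with `animal_a`, `animal_b` (lexicographically ordered,
#'   `animal_a < animal_b`), `site_id`, `t_start`, `t_end`, `duration`.
#' @export
extract_encounters <- function(stays) {
  assert_columns(stays, c("animal_id", "site_id", "t_in", "t_out"))
  empty <- tibble(animal_a = character(), animal_b = character(),
                  site_id = character(), t_start = double(),
                  t_end = double(), duration = double())
  if (nrow(stays) < 2) return(empty)
  res <- lapply(split(stays, stays$site_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    s <- s[order(s$t_in), ]
    # for each stay i, candidate partners are later-starting stays j with
    # t_in[j] < t_out[i]; t_in sorted makes them a contiguous run.
    n <- nrow(s)
    last <- findInterval(s$t_out, s$t_in, left.open = TRUE)
    i <- rep.int(seq_len(n), pmax(last - seq_len(n), 0L))
    if (length(i) == 0) return(NULL)
    j <- sequence(pmax(last - seq_len(n), 0L), from = seq_len(n) + 1L)
    keep <- s$animal_id[i] != s$animal_id[j]
    i <- i[keep]; j <- j[keep]
    if (length(i) == 0) return(NULL)
    t_start <- pmax(s$t_in[i], s$t_in[j])
    t_end <- pmin(s$t_out[i], s$t_out[j])
    ok <- t_end > t_start
    i <- i[ok]; j <- j[ok]; t_start <- t_start[ok]; t_end <- t_end[ok]
    if (length(i) == 0) return(NULL)
    pair <- canonical_pair(s$animal_id[i], s$animal_id[j])
    tibble(animal_a = pair$first, animal_b = pair$second,
           site_id = s$site_id[1], t_start = t_start, t_end = t_end,
           duration = t_end - t_start)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$t_start, .data$animal_a, .data$animal_b,
                 .data$t_end)
}

#' Summarise transits into per-bridge statistics
#'
#' Pools transits over unordered site pairs (a trip and its reverse are
#' mirror images for landscape purposes), keeps pairs crossed at least
#' `min_crossings` times, and summarises each with its crossing count, the
#' straight-line distance between site centres and the *median* transit
#' duration. The median is used because transit-time distributions are
#' heavily right-skewed: rare day-long excursions would otherwise dominate
#' the mean. Self-transits are excluded (a zero-length bridge has no
#' spatial extent).
#'
#' @param transits Tibble from [stays_to_transits()].
#' @param layout Site layout (see [read_site_layout()]).
#' @param min_crossings Minimum pooled crossing count for a pair to form a
#'   bridge. Default 50, the population-level filter; use 10 for individual
#'   landscapes.
#' @return Tibble with `site_a`, `site_b`, `n_cross`, `distance` (m),
#'   `median_duration` (s).
#' @export
bridge_summary <- function(transits, layout, min_crossings = 50) {
  assert_columns(transits, c("from_site", "to_site", "duration"))
  validate_layout(layout)
  if (min_crossings < 1) abort("`min_crossings` must be >= 1.")
  unknown <- setdiff(unique(c(transits$from_site, transits$to_site)),
                     layout$site_id)
  if (length(unknown) > 0) {
    abort(sprintf("Site(s) %s appear in transits but not in the layout.",
                  paste(unknown, collapse = ", ")))
  }
  tr <- transits[transits$from_site != transits$to_site, ]
  if (nrow(tr) == 0) {
    return(tibble(site_a = character(), site_b = character(),
                  n_cross = integer(), distance = double(),
                  median_duration = double()))
  }
  pair <- canonical_pair(tr$from_site, tr$to_site)
  tr$site_a <- pair$first
  tr$site_b <- pair$second
  pos <- setNames(split(c(layout$x, layout$y), rep(layout$site_id, 2)), layout$site_id)
  out <- tr |>
    dplyr::group_by(.data$site_a, .data$site_b) |>
    dplyr::summarise(n_cross = dplyr::n(),
                     median_duration = stats::median(.data$duration),
                     .groups = "drop") |>
    dplyr::filter(.data$n_cross >= min_crossings)
  xa <- layout$x[match(out$site_a, layout$site_id)]
  ya <- layout$y[match(out$site_a, layout$site_id)]
  xb <- layout$x[match(out$site_b, layout$site_id)]
  yb <- layout$y[match(out$site_b, layout$site_id)]
  out$distance <- sqrt((xa - xb)^2 + (ya - yb)^2)
  out[, c("site_a", "site_b", "n_cross", "distance", "median_duration")]
}

#' Calibrate the effective transit speed
#'
#' The effective velocity is the assumed along-path speed of an animal in
#' transit. It is calibrated on the "straightest" bridge: the pair with the
#' largest ratio of straight-line distance to median transit time is taken
#' to have been crossed in a straight line (zero diffusion), so the
#' effective speed equals the maximum of `distance / median_duration` over
#' all bridges. By construction every bridge then receives a non-negative
#' diffusion coefficient from [bridge_diffusion()].
#'
#' @param bridges Tibble from [bridge_summary()].
#' @return Effective speed in m/s (a single number).
#' @export
calibrate_vbar <- function(bridges) {
  assert_columns(bridges, c("distance", "median_duration"))
  b <- bridges[bridges$distance > 0, ]
  if (nrow(b) == 0) {
    abort("Cannot calibrate the effective speed: no bridge with positive length (degenerate layout).")
  }
  max(b$distance / b$median_duration)
}
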