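# Independent oracles and fixture builders shared across the test files.

# Brute-force run-length oracle: a per-minute state machine over a label
# string ("H" home, "A" away, "M" missing), deliberately structured
# differently from the vectorized implementation it checks. Labels index
# minutes from midnight, so runs are additionally split at each 1440-minute
# day boundary (excursions split at midnight by design).
oracle_segment <- function(labels, gap_bridge = 0, min_dur = 1,
                           day_len = 1440L) {
  chunk_id <- (seq_along(labels) - 1L) %/% day_len
  parts <- lapply(unique(chunk_id), function(k) {
    res <- oracle_segment_one_day(labels[chunk_id == k], gap_bridge, min_dur)
    res$start <- res$start + k * day_len
    res$end <- res$end + k * day_len
    res
  })
  do.call(rbind, parts)
}

oracle_segment_one_day <- function(labels, gap_bridge = 0, min_dur = 1) {
  runs <- list()
  start <- NA_integer_
  last_away <- NA_integer_
  pending_missing <- 0L
  close_run <- function() {
    if (!is.na(start)) runs[[length(runs) + 1L]] <<- c(start, last_away)
    start <<- NA_integer_
    pending_missing <<- 0L
  }
  for (t in seq_along(labels)) {
    lab <- labels[t]
    if (lab == "A") {
      if (is.na(start)) {
        start <- t
      } else if (pending_missing > gap_bridge) {
        close_run()
        start <- t
      }
      pending_missing <- 0L
      last_away <- t
    } else if (lab == "H") {
      close_run()
    } else {
      if (!is.na(start)) pending_missing <- pending_missing + 1L
    }
  }
  close_run()
  if (length(runs) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      duration = integer()))
  }
  out <- data.frame(start = vapply(runs, `[`, 1L, 1),
                    end = vapply(runs, `[`, 1L, 2))
  out$duration <- out$end - out$start + 1L
  out[out$duration >= min_dur, , drop = FALSE]
}

# Turn a label string into a labeled one-day GPS tibble (missing minutes
# simply absent) suitable for segment_excursions().
labels_to_trace <- function(labels, participant = "p1", visit = "baseline",
                            day = as.Date("2014-03-03")) {
  t0 <- as.numeric(as.POSIXct(day, tz = "UTC"))
  present <- which(labels != "M")
  tibble::tibble(
    participant_id = participant, visit = visit,
    timestamp = as.POSIXct(t0 + (present - 1) * 60, origin = "1970-01-01",
                           tz = "UTC"),
    lat = 39, lon = -76,
    label = ifelse(labels[present] == "A", "away", "home"))
}

random_labels <- function(len, p_away = 0.3, p_missing = 0.15) {
  sample(c("A", "H", "M"), len, replace = TRUE,
         prob = c(p_away, 1 - p_away - p_missing, p_missing))
}

# A one-day GPS trace with fixes in n_window distinct minutes of the
# 06:00-22:00 window (and optionally extra night fixes for home finding).
window_day_trace <- function(n_window, participant = "p1",
                             visit = "baseline",
                             day = as.Date("2014-03-03"),
                             with_night = TRUE) {
  t0 <- as.numeric(as.POSIXct(day, tz = "UTC"))
  mins <- if (n_window > 0) 360 + seq_len(n_window) - 1 else integer()
  if (with_night) mins <- c(125, mins)
  tibble::tibble(
    participant_id = participant, visit = visit,
    timestamp = as.POSIXct(t0 + mins * 60, origin = "1970-01-01",
                           tz = "UTC"),
    lat = 39, lon = -76.5)
}

# Latitude offset whose haversine distance is exactly `meters` due north
# (frozen from an independently computed conversion; R = 6,371,000 m).
lat_offset_m <- function(meters) meters / 6371000 * 180 / pi

# Cohort fall-status fixture reconstructed from marginal counts: returns
# falls + parsed months for n_total participants of whom n_faller fell,
# n_recurrent fell more than once, n_injurious had an injurious fall and
# n_recurrent_injurious had more than one injurious fall.
margin_fall_fixture <- function(n_total, n_faller, n_recurrent,
                                n_injurious, n_recurrent_injurious,
                                start = as.Date("2014-03-01")) {
  stopifnot(n_recurrent_injurious <= n_recurrent,
            n_recurrent_injurious <= n_injurious,
            n_injurious <= n_faller, n_recurrent <= n_faller,
            n_faller <= n_total)
  b <- n_recurrent - n_recurrent_injurious
  inj_left <- n_injurious - n_recurrent_injurious
  rec_inj1 <- min(b, inj_left)
  single_inj <- inj_left - rec_inj1
  singles <- n_faller - n_recurrent
  stopifnot(single_inj <= singles)
  profile <- rbind(
    matrix(rep(c(2, 2), n_recurrent_injurious), ncol = 2, byrow = TRUE),
    matrix(rep(c(2, 1), rec_inj1), ncol = 2, byrow = TRUE),
    matrix(rep(c(2, 0), b - rec_inj1), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 1), single_inj), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), singles - single_inj), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), n_total - n_faller), ncol = 2, byrow = TRUE))
  ids <- sprintf("F%04d", seq_len(n_total))
  months <- format(seq(start, by = "month", length.out = 12), "%Y-%m")
  falls <- purrr::map_dfr(seq_len(n_total), function(i) {
    k <- profile[i, 1]
    if (k == 0) return(NULL)
    tibble::tibble(participant_id = ids[i],
                   date = seq(start, by = "month", length.out = 12)[seq_len(k)] + 14,
                   injurious = as.integer(seq_len(k) <= profile[i, 2]))
  })
  month_status <- tidyr::expand_grid(participant_id = ids, month = months) |>
    dplyr::mutate(returned = 1L)
  calendar <- dplyr::transmute(falls, participant_id, date, fell = 1L)
  list(falls = falls, calendar = calendar, month_status = month_status,
       months = parse_calendars(calendar, month_status))
}
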