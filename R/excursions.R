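# Away-from-home excursion quantification from minute-epoch GPS traces.
#
# The pipeline is: dedupe fixes -> estimate the home anchor from night-time
# (02:00-04:00) fixes -> label every fix home/away against a 50-m home
# margin -> valid-day quality control (>= 80% of the 960 minutes between
# 06:00 and 22:00) -> run-length segmentation of away minutes into
# excursions -> the three weekly parameters (daily excursions, daily time
# away, time per excursion), averaged over valid days only.

#' Great-circle (haversine) distance in meters
#'
#' Distance between WGS84 coordinate pairs on a sphere of radius
#' 6,371,000 m. Vectorized over both arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in meters.
#' @export
#' @examples
#' haversine_m(0, 0, 1, 0) # one degree along a meridian, ~111.2 km
haversine_m <- function(lat1, lon1, lat2, lon2) {
  assert_latlon(lat1, lon1)
  assert_latlon(lat2, lon2)
  rad <- pi / 180
  p1 <- lat1 * rad
  p2 <- lat2 * rad
  a <- sin((p2 - p1) / 2)^2 +
    cos(p1) * cos(p2) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

#' Deduplicate minute fixes
#'
#' GPS loggers occasionally emit more than one fix in a minute. One fix per
#' (participant, visit, minute) is kept -- the first after truncating
#' timestamps to the whole minute -- and a warning reports how many were
#' dropped.
#'
#' @param gps tibble with columns `participant_id`, `visit`, `timestamp`
#'   (POSIXct), `lat`, `lon`.
#' @return tibble with truncated timestamps, strictly one row per
#'   participant-visit-minute, ordered in time.
#' @export
dedupe_fixes <- function(gps) {
  assert_columns(gps, c("participant_id", "visit", "timestamp", "lat", "lon"),
                 "GPS table")
  assert_latlon(gps$lat, gps$lon)
  gps <- gps |>
    dplyr::mutate(timestamp = truncate_to_minute(.data$timestamp)) |>
    dplyr::arrange(.data$participant_id, .data$visit, .data$timestamp)
  n <- nrow(gps)
  dup <- if (n < 2) logical(n) else {
    c(FALSE,
      gps$participant_id[-1] == gps$participant_id[-n] &
        gps$visit[-1] == gps$visit[-n] &
        as.numeric(gps$timestamp[-1]) == as.numeric(gps$timestamp[-n]))
  }
  if (any(dup)) {
    warn(sprintf("dropped %d duplicate minute fix(es); kept the first of each",
                 sum(dup)))
    gps <- gps[!dup, , drop = FALSE]
  }
  tibble::as_tibble(gps)
}

#' Estimate the home anchor from night-time fixes
#'
#' The home anchor is the componentwise median of all fixes recorded in the
#' night window (default 02:00-04:00, half-open), pooled over the whole
#' week. The median is robust to GPS jitter and the occasional night away.
#'
#' @param gps deduplicated GPS tibble (see [dedupe_fixes()]).
#' @param night_window length-2 numeric, start/end hour of the night window
#'   (half-open interval).
#' @return tibble with one row per participant-visit: `home_lat`,
#'   `home_lon`, `n_night_fixes`.
#' @export
estimate_home <- function(gps, night_window = c(2, 4)) {
  assert_columns(gps, c("participant_id", "visit", "timestamp", "lat", "lon"),
                 "GPS table")
  lo <- night_window[1] * 60
  hi <- night_window[2] * 60
  mod <- minute_of_day(gps$timestamp)
  night <- gps[mod >= lo & mod < hi, , drop = FALSE]
  homes <- night |>
    dplyr::group_by(.data$participant_id, .data$visit) |>
    dplyr::summarise(home_lat = median(.data$lat),
                     home_lon = median(.data$lon),
                     n_night_fixes = dplyr::n(),
                     .groups = "drop")
  all_groups <- dplyr::distinct(gps, .data$participant_id, .data$visit)
  missing <- dplyr::anti_join(all_groups, homes,
                              by = c("participant_id", "visit"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "home unidentifiable (no fixes in the night window) for: ",
      paste(missing$participant_id, missing$visit, sep = "/", collapse = ", ")))
  }
  homes
}

#' Label fixes home or away against the home margin
#'
#' A fix is `home` iff its haversine distance to the anchor is at most
#' `radius_m` (boundary inclusive), otherwise `away`.
#'
#' @param gps deduplicated GPS tibble.
#' @param homes home anchors from [estimate_home()].
#' @param radius_m home-margin radius in meters (default 50).
#' @return `gps` with added columns `dist_home_m` and `label`
#'   (`"home"`/`"away"`).
#' @export
classify_fixes <- function(gps, homes, radius_m = 50) {
  if (!is.numeric(radius_m) || radius_m <= 0) {
    abort("`radius_m` must be a positive number")
  }
  labeled <- dplyr::inner_join(gps, homes, by = c("participant_id", "visit"))
  if (nrow(labeled) != nrow(gps)) {
    abort("some participant-visits in `gps` have no home anchor")
  }
  labeled |>
    dplyr::mutate(
      dist_home_m = haversine_m(.data$lat, .data$lon,
                                .data$home_lat, .data$home_lon),
      label = dplyr::if_else(.data$dist_home_m <= radius_m, "home", "away")
    ) |>
    dplyr::select(-"n_night_fixes")
}

#' Valid-day quality control
#'
#' A calendar day is valid when fixes cover at least `valid_fraction`
#' (default 0.80) of the 960 minutes in the day window (default
#' 06:00-22:00, half-open). One record is produced per calendar date
#' present in the trace.
#'
#' @param gps deduplicated GPS tibble.
#' @param valid_fraction minimum coverage of the day window.
#' @param day_window length-2 numeric, start/end hour of the day window.
#' @return tibble with one row per participant-visit-date:
#'   `n_window_minutes`, `coverage`, `valid`.
#' @export
qc_valid_days <- function(gps, valid_fraction = 0.8, day_window = c(6, 22)) {
  assert_proportion(valid_fraction, "valid_fraction")
  lo <- day_window[1] * 60
  hi <- day_window[2] * 60
  window_size <- hi - lo
  mod <- minute_of_day(gps$timestamp)
  gps |>
    dplyr::mutate(date = date_of(.data$timestamp),
                  in_window = mod >= lo & mod < hi) |>
    dplyr::group_by(.data$participant_id, .data$visit, .data$date) |>
    dplyr::summarise(n_window_minutes = sum(.data$in_window),
                     .groups = "drop") |>
    dplyr::mutate(coverage = .data$n_window_minutes / window_size,
                  valid = .data$coverage >= valid_fraction)
}

#' Participant-visit inclusion by minimum valid days
#'
#' @param day_records output of [qc_valid_days()].
#' @param min_valid_days minimum number of valid days required (default 2).
#' @return tibble with one row per participant-visit: `n_valid_days`,
#'   `included`.
#' @export
meets_min_valid_days <- function(day_records, min_valid_days = 2) {
  day_records |>
    dplyr::group_by(.data$participant_id, .data$visit) |>
    dplyr::summarise(n_valid_days = sum(.data$valid), .groups = "drop") |>
    dplyr::mutate(included = .data$n_valid_days >= min_valid_days)
}

# Core run-length segmentation on one day's sorted present minutes.
# minute_idx: absolute minute indices (sorted, unique); is_away: logical.
# A run of away minutes breaks at any intervening home minute, or at a gap
# of unobserved minutes longer than gap_bridge_min. Bridged gap minutes
# count toward the duration (duration = span from first to last away
# minute of the run).
segment_minutes <- function(minute_idx, is_away, gap_bridge_min = 0,
                            min_excursion_min = 1) {
  pos <- which(is_away)
  if (length(pos) == 0) {
    return(tibble::tibble(start_min = integer(), end_min = integer(),
                          duration_min = integer()))
  }
  m <- minute_idx[pos]
  if (length(pos) == 1) {
    brk <- logical(0)
  } else {
    home_between <- diff(pos) > 1
    gap_missing <- diff(m) - 1L - (diff(pos) - 1L)
    brk <- home_between | (gap_missing > gap_bridge_min)
  }
  run <- cumsum(c(TRUE, brk))
  start_min <- as.integer(tapply(m, run, min))
  end_min <- as.integer(tapply(m, run, max))
  out <- tibble::tibble(start_min = start_min, end_min = end_min,
                        duration_min = end_min - start_min + 1L)
  out[out$duration_min >= min_excursion_min, , drop = FALSE]
}

#' Segment labeled fixes into excursions
#'
#' Each maximal run of away-labeled minutes within a calendar day is one
#' excursion. Runs are broken by home-labeled minutes, by gaps of
#' unobserved minutes longer than `gap_bridge_min` (default 0: any missing
#' minute breaks a run), and at midnight. Bridged gap minutes count toward
#' the duration; excursions shorter than `min_excursion_min` are dropped.
#'
#' @param labeled output of [classify_fixes()].
#' @param gap_bridge_min maximum run of unobserved minutes to bridge
#'   between away minutes (default 0 = off).
#' @param min_excursion_min minimum duration in minutes (default 1).
#' @return tibble with one row per excursion: `participant_id`, `visit`,
#'   `date`, `start`, `end` (timestamps of first and last away minute),
#'   `duration_min`.
#' @export
segment_excursions <- function(labeled, gap_bridge_min = 0,
                               min_excursion_min = 1) {
  assert_columns(labeled, c("participant_id", "visit", "timestamp", "label"),
                 "labeled GPS table")
  labeled |>
    dplyr::mutate(date = date_of(.data$timestamp),
                  .minute = minute_index(.data$timestamp)) |>
    dplyr::arrange(.data$participant_id, .data$visit, .data$.minute) |>
    dplyr::group_by(.data$participant_id, .data$visit, .data$date) |>
    dplyr::reframe(segment_minutes(.data$.minute, .data$label == "away",
                                   gap_bridge_min, min_excursion_min)) |>
    dplyr::mutate(
      start = as.POSIXct(.data$start_min * 60, origin = "1970-01-01",
                         tz = "UTC"),
      end = as.POSIXct(.data$end_min * 60, origin = "1970-01-01", tz = "UTC")
    ) |>
    dplyr::select("participant_id", "visit", "date", "start", "end",
                  "duration_min")
}

#' Weekly excursion parameters
#'
#' Summarises excursions into the three away-from-home parameters, averaged
#' over valid days only: average number of daily excursions, average daily
#' time away from home (hours), and average time per excursion (hours,
#' undefined -- `NA` -- when there are no excursions). Excursions on
#' invalid days are discarded; away time outside the 06:00-22:00 window on
#' a valid day still counts (the window defines validity, not the
#' measurement).
#'
#' @param excursions output of [segment_excursions()].
#' @param day_records output of [qc_valid_days()].
#' @param min_valid_days minimum valid days for inclusion (default 2).
#' @return tibble with one row per participant-visit: `n_valid_days`,
#'   `n_excursions`, `away_minutes`, `avg_daily_excursions`,
#'   `avg_daily_time_away_h`, `avg_time_per_excursion_h`, `included`.
#' @export
summarize_excursions <- function(excursions, day_records, min_valid_days = 2) {
  valid_days <- day_records[day_records$valid, , drop = FALSE]
  kept <- dplyr::semi_join(
    excursions, valid_days,
    by = c("participant_id", "visit", "date"))
  totals <- kept |>
    dplyr::group_by(.data$participant_id, .data$visit) |>
    dplyr::summarise(n_excursions = dplyr::n(),
                     away_minutes = sum(.data$duration_min),
                     .groups = "drop")
  meets_min_valid_days(day_records, min_valid_days) |>
    dplyr::left_join(totals, by = c("participant_id", "visit")) |>
    dplyr::mutate(
      n_excursions = dplyr::coalesce(.data$n_excursions, 0L),
      away_minutes = dplyr::coalesce(.data$away_minutes, 0L),
      avg_daily_excursions = ifelse(.data$n_valid_days > 0,
                                    .data$n_excursions / .data$n_valid_days,
                                    NA_real_),
      avg_daily_time_away_h = ifelse(.data$n_valid_days > 0,
                                     .data$away_minutes / .data$n_valid_days / 60,
                                     NA_real_),
      avg_time_per_excursion_h = ifelse(.data$n_excursions > 0,
                                        .data$away_minutes / .data$n_excursions / 60,
                                        NA_real_)
    ) |>
    dplyr::select("participant_id", "visit", "n_valid_days", "n_excursions",
                  "away_minutes", "avg_daily_excursions",
                  "avg_daily_time_away_h", "avg_time_per_excursion_h",
                  "included")
}

#' End-to-end excursion summary from raw GPS fixes
#'
#' Runs the full GPS stage: deduplication, home anchoring, home/away
#' labeling, valid-day QC, segmentation and weekly summaries.
#'
#' @inheritParams dedupe_fixes
#' @inheritParams classify_fixes
#' @inheritParams qc_valid_days
#' @inheritParams segment_excursions
#' @inheritParams summarize_excursions
#' @param night_window night window (hours) for home anchoring.
#' @return list with components `summary` (per participant-visit tibble,
#'   see [summarize_excursions()]), `excursions`, `day_records`, `homes`.
#' @export
#' @examples
#' week <- simulate_gps_week("p1", "baseline", home_lat = 39.29,
#'                           home_lon = -76.61, daily_rate = 2,
#'                           noise_sd_m = 0, missing_day_prob = 0,
#'                           missing_minute_prob = 0, seed = 1)
#' res <- excursion_summary(week$gps)
#' res$summary
excursion_summary <- function(gps, radius_m = 50, valid_fraction = 0.8,
                              min_valid_days = 2, gap_bridge_min = 0,
                              min_excursion_min = 1, night_window = c(2, 4),
                              day_window = c(6, 22)) {
  gps <- dedupe_fixes(gps)
  homes <- estimate_home(gps, night_window)
  labeled <- classify_fixes(gps, homes, radius_m)
  day_records <- qc_valid_days(gps, valid_fraction, day_window)
  excursions <- segment_excursions(labeled, gap_bridge_min, min_excursion_min)
  summary <- summarize_excursions(excursions, day_records, min_valid_days)
  list(summary = summary, excursions = excursions,
       day_records = day_records, homes = homes)
}
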