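# Synthetic cohort generator with known latent truth: minute-epoch GPS
# weeks around a fixed home, monthly falls calendars with injury marks,
# paired-eye 24-2 visual fields, and baseline covariates. Every downstream
# stage of the pipeline is testable against the planted truth.

EARTH_RADIUS_M <- 6371000

# meters -> degrees at a given latitude (local tangent-plane conversion)
meters_to_lat <- function(dy) dy / EARTH_RADIUS_M * 180 / pi
meters_to_lon <- function(dx, lat) {
  dx / (EARTH_RADIUS_M * cos(lat * pi / 180)) * 180 / pi
}

#' Cohort scenario: the knobs of the synthetic generator
#'
#' Defaults emulate the study conditions of a one-year falls cohort of
#' older adults with glaucoma: 192 participants, two 7-day minute-epoch
#' GPS weeks (baseline and year 1) around a fixed home, ~45% fallers with
#' ~44% of fallers falling more than once, 55.2% of falls injurious,
#' excursion counts Poisson with ~2.5 excursions/day and log-normal
#' durations with median 90 min, integrated-field sensitivities around
#' 27.5 dB, and Table-1-like covariate margins.
#'
#' @param n_participants cohort size.
#' @param seed default RNG seed used by [simulate_cohort()].
#' @param faller_fraction proportion of participants who fall at least
#'   once during follow-up.
#' @param recurrent_falls_mean mean number of falls beyond the first for
#'   fallers (Poisson); 0.575 gives P(>1 fall | faller) ~= 0.44.
#' @param injurious_given_fall per-fall probability of injury.
#' @param base_daily_excursion_rate Poisson mean of daily excursion counts.
#' @param excursion_rate_dispersion shape of the mean-1 gamma frailty
#'   multiplying each participant's excursion rate (variance 1/shape).
#'   Between-participant heterogeneity in mobility makes weekly counts
#'   negative binomial rather than Poisson, as in real cohorts.
#' @param irr_fall_on_excursions multiplicative change of fallers' year-1
#'   excursion rate (1 = falls leave mobility unchanged).
#' @param excursion_duration_log_mean,excursion_duration_log_sd log-normal
#'   parameters of per-excursion durations, in log-minutes.
#' @param gps_noise_sd_m GPS jitter (per-axis Gaussian SD, meters).
#' @param missing_day_prob probability a whole GPS day is unrecorded.
#' @param missing_minute_prob probability an individual at-home minute is
#'   dropped (non-wear/indoor signal loss; away minutes persist).
#' @param missing_month_prob probability a falls calendar month is never
#'   returned.
#' @param vf_mean_db,vf_sd_db between-participant distribution of the
#'   latent per-eye field sensitivity (dB). The pointwise-max binocular
#'   integration adds about +3.6 dB over this latent level, so the default
#'   of 24 dB centres the integrated-field mean sensitivity near 28 dB.
#' @param vf_point_sd_db within-field point-to-point noise (dB).
#' @param age_mean,age_sd,male_prop,black_prop,comorbid_gt1_prop,polypharmacy_prop
#'   covariate distributions.
#' @param home_centre_lat,home_centre_lon,home_spread_deg home coordinates
#'   are drawn uniformly in a square of this half-width around the centre.
#' @return validated list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_participants = 192,
                            seed = 1L,
                            faller_fraction = 0.453,
                            recurrent_falls_mean = 0.575,
                            injurious_given_fall = 0.552,
                            base_daily_excursion_rate = 2.5,
                            excursion_rate_dispersion = 2.5,
                            irr_fall_on_excursions = 1,
                            excursion_duration_log_mean = log(90),
                            excursion_duration_log_sd = 0.8,
                            gps_noise_sd_m = 10,
                            missing_day_prob = 0.12,
                            missing_minute_prob = 0.05,
                            missing_month_prob = 0.03,
                            vf_mean_db = 24,
                            vf_sd_db = 3.2,
                            vf_point_sd_db = 4,
                            age_mean = 70.1, age_sd = 7,
                            male_prop = 0.505, black_prop = 0.281,
                            comorbid_gt1_prop = 0.63,
                            polypharmacy_prop = 0.307,
                            home_centre_lat = 39.29,
                            home_centre_lon = -76.61,
                            home_spread_deg = 0.25) {
  for (p in c("faller_fraction", "injurious_given_fall", "missing_day_prob",
              "missing_minute_prob", "missing_month_prob", "male_prop",
              "black_prop", "comorbid_gt1_prop", "polypharmacy_prop")) {
    assert_proportion(get(p), p)
  }
  for (p in c("recurrent_falls_mean", "base_daily_excursion_rate",
              "excursion_rate_dispersion",
              "irr_fall_on_excursions", "excursion_duration_log_sd",
              "gps_noise_sd_m", "vf_sd_db", "vf_point_sd_db", "age_sd")) {
    assert_nonnegative(get(p), p)
  }
  if (n_participants < 1) abort("`n_participants` must be >= 1")
  n_participants <- as.integer(n_participants)
  seed <- as.integer(seed)
  structure(mget(names(formals(cohort_scenario))), class = "cohort_scenario")
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("<cohort_scenario>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Plan one day's excursions: Poisson count, log-normal integer durations,
# placed without overlap inside the 06:00-22:00 window with at least one
# home minute between consecutive excursions. Returns start/duration in
# minutes-of-day.
plan_day_excursions <- function(daily_rate, log_mean, log_sd,
                                window = c(360L, 1320L)) {
  span <- window[2] - window[1]
  n <- rpois(1, daily_rate)
  if (n == 0) {
    return(tibble::tibble(start = integer(), duration = integer()))
  }
  dur <- pmax(1L, as.integer(round(rlnorm(n, log_mean, log_sd))))
  dur <- pmin(dur, span)
  # drop excursions (longest first) until the day can hold them all
  while (sum(dur) + (length(dur) - 1L) > span) {
    dur <- dur[-which.max(dur)]
  }
  n <- length(dur)
  if (n == 0) {
    return(tibble::tibble(start = integer(), duration = integer()))
  }
  free <- span - sum(dur) - (n - 1L)
  extra <- as.integer(rmultinom(1, free, rep(1, n + 1)))
  # leading gap, then >=1 home minute between consecutive excursions;
  # the trailing slack extra[n + 1] stays unused at the end of the window
  gaps <- if (n == 1) extra[1] else c(extra[1], extra[2:n] + 1L)
  start <- window[1] + cumsum(gaps) + c(0L, cumsum(dur)[-n])
  tibble::tibble(start = start, duration = dur)
}

# Minute positions for one excursion: a random-walk displacement around a
# point 300-1500 m from home, radially clamped to stay > 200 m away so the
# planted home/away labelling is unambiguous.
excursion_track_m <- function(n_min, step_sd_m = 30) {
  bearing <- runif(1, 0, 2 * pi)
  dist <- runif(1, 300, 1500)
  cx <- dist * sin(bearing)
  cy <- dist * cos(bearing)
  x <- cx + cumsum(rnorm(n_min, 0, step_sd_m))
  y <- cy + cumsum(rnorm(n_min, 0, step_sd_m))
  r <- sqrt(x^2 + y^2)
  clamp <- r < 210
  if (any(clamp)) {
    scale <- 210 / r[clamp]
    x[clamp] <- x[clamp] * scale
    y[clamp] <- y[clamp] * scale
  }
  cbind(x, y)
}

#' Simulate one 7-day minute-epoch GPS week
#'
#' Generates a full week of minute-aligned fixes around a fixed home.
#' Away episodes are contiguous blocks placed inside 06:00-22:00 at
#' > 200 m from home; all other minutes (including the whole 02:00-04:00
#' night window) are at home plus Gaussian jitter. Whole days are dropped
#' with `missing_day_prob`; individual home minutes are additionally
#' dropped with `missing_minute_prob` (non-wear and indoor signal loss
#' occur at home -- while out on an excursion the device is outdoors and
#' keeps its fix).
#'
#' @param participant_id,visit identifiers copied into the output.
#' @param home_lat,home_lon planted home coordinate (WGS84 degrees).
#' @param daily_rate Poisson mean of excursions per day (>= 0).
#' @param duration_log_mean,duration_log_sd log-normal duration parameters
#'   (log-minutes).
#' @param noise_sd_m per-axis GPS jitter SD in meters.
#' @param missing_day_prob,missing_minute_prob missingness probabilities.
#' @param start_date first calendar day of the week.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return list with `gps` (tibble of fixes) and `truth` (tibble with one
#'   row per day: planted `n_excursions`, `away_minutes`, `day_observed`).
#' @export
simulate_gps_week <- function(participant_id, visit, home_lat, home_lon,
                              daily_rate,
                              duration_log_mean = log(90),
                              duration_log_sd = 0.8,
                              noise_sd_m = 10,
                              missing_day_prob = 0,
                              missing_minute_prob = 0,
                              start_date = as.Date("2014-03-03"),
                              seed = NULL) {
  assert_nonnegative(daily_rate, "daily_rate")
  assert_nonnegative(noise_sd_m, "noise_sd_m")
  assert_proportion(missing_day_prob, "missing_day_prob")
  assert_proportion(missing_minute_prob, "missing_minute_prob")
  if (!is.null(seed)) set.seed(seed)
  days <- start_date + 0:6
  day_gps <- vector("list", 7)
  truth <- vector("list", 7)
  for (d in seq_along(days)) {
    plan <- plan_day_excursions(daily_rate, duration_log_mean,
                                duration_log_sd)
    minute <- 0:1439
    away <- rep(FALSE, 1440)
    for (k in seq_len(nrow(plan))) {
      away[(plan$start[k] + 1):(plan$start[k] + plan$duration[k])] <- TRUE
    }
    dx <- rnorm(1440, 0, noise_sd_m)
    dy <- rnorm(1440, 0, noise_sd_m)
    for (k in seq_len(nrow(plan))) {
      idx <- (plan$start[k] + 1):(plan$start[k] + plan$duration[k])
      track <- excursion_track_m(length(idx))
      dx[idx] <- dx[idx] + track[, 1]
      dy[idx] <- dy[idx] + track[, 2]
    }
    day_observed <- runif(1) >= missing_day_prob
    # minute dropout models non-wear and indoor signal loss, which happen
    # at home (sleeping, bathing); minutes on an excursion are outdoors
    # with reliable fixes and are only lost with the whole day
    keep <- if (day_observed) {
      away | runif(1440) >= missing_minute_prob
    } else {
      rep(FALSE, 1440)
    }
    truth[[d]] <- tibble::tibble(
      date = days[d],
      n_excursions = nrow(plan),
      away_minutes = as.integer(sum(plan$duration)),
      day_observed = day_observed)
    if (any(keep)) {
      ts <- as.POSIXct(as.numeric(as.POSIXct(days[d], tz = "UTC")) +
                         minute[keep] * 60,
                       origin = "1970-01-01", tz = "UTC")
      day_gps[[d]] <- tibble::tibble(
        participant_id = participant_id,
        visit = visit,
        timestamp = ts,
        lat = home_lat + meters_to_lat(dy[keep]),
        lon = home_lon + meters_to_lon(dx[keep], home_lat))
    }
  }
  gps <- dplyr::bind_rows(day_gps)
  if (nrow(gps) == 0) {
    gps <- tibble::tibble(participant_id = character(), visit = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          lat = numeric(), lon = numeric())
  }
  list(gps = gps,
       truth = dplyr::mutate(dplyr::bind_rows(truth),
                             participant_id = participant_id, visit = visit,
                             .before = 1))
}

#' Simulate one year of monthly falls calendars
#'
#' Either a fixed number of falls (`n_falls`, placed on distinct uniformly
#' chosen days of the year) or a per-month fall probability
#' (`p_fall_month`, at most one fall per month on a random day). Each fall
#' is injurious with probability `p_injurious`. Calendar day-flags are
#' consistent with the emitted fall records; months are marked missing
#' (never returned within the collectibility horizon) with probability
#' `missing_month_prob`.
#'
#' @param participant_id identifier copied into the output.
#' @param p_injurious per-fall injury probability.
#' @param n_falls exact number of falls to plant (mutually exclusive with
#'   `p_fall_month`).
#' @param p_fall_month per-month probability of one fall.
#' @param start first day of the follow-up year (a month boundary).
#' @param missing_month_prob probability each month's calendar is missing.
#' @param seed optional seed.
#' @return list with `calendar` (participant_id, date, fell), `month_status`
#'   (participant_id, month, returned) and `falls` (participant_id, date,
#'   injurious).
#' @export
simulate_falls_year <- function(participant_id, p_injurious,
                                n_falls = NULL, p_fall_month = NULL,
                                start = as.Date("2014-03-01"),
                                missing_month_prob = 0, seed = NULL) {
  assert_proportion(p_injurious, "p_injurious")
  assert_proportion(missing_month_prob, "missing_month_prob")
  if (is.null(n_falls) == is.null(p_fall_month)) {
    abort("give exactly one of `n_falls` or `p_fall_month`")
  }
  if (!is.null(seed)) set.seed(seed)
  month_starts <- seq(start, by = "month", length.out = 12)
  end <- seq(start, by = "month", length.out = 13)[13] - 1
  all_days <- seq(start, end, by = "day")
  if (!is.null(n_falls)) {
    if (n_falls < 0 || n_falls > length(all_days)) {
      abort("`n_falls` must be between 0 and the number of follow-up days")
    }
    fall_days <- sort(sample(all_days, n_falls))
  } else {
    assert_proportion(p_fall_month, "p_fall_month")
    fall_days <- as.Date(character())
    for (m in seq_len(12)) {
      if (runif(1) < p_fall_month) {
        month_days <- seq(month_starts[m],
                          c(month_starts[-1], end + 1)[m] - 1, by = "day")
        fall_days <- c(fall_days, sample(month_days, 1))
      }
    }
    fall_days <- sort(fall_days)
  }
  injurious <- as.integer(runif(length(fall_days)) < p_injurious)
  falls <- tibble::tibble(participant_id = participant_id,
                          date = fall_days, injurious = injurious)
  calendar <- tibble::tibble(
    participant_id = participant_id,
    date = all_days,
    fell = as.integer(all_days %in% fall_days))
  month_status <- tibble::tibble(
    participant_id = participant_id,
    month = format(month_starts, "%Y-%m"),
    returned = as.integer(runif(12) >= missing_month_prob))
  list(calendar = calendar, month_status = month_status, falls = falls)
}

# One participant's paired-eye 24-2 fields around a latent sensitivity.
simulate_vf_pair <- function(participant_id, latent_db, point_sd_db) {
  grid <- vf_grid_24_2()
  purrr::map_dfr(c("OD", "OS"), function(eye) {
    eye_mean <- latent_db + rnorm(1, 0, 1)
    sens <- pmin(40, pmax(0, round(eye_mean + rnorm(nrow(grid), 0,
                                                    point_sd_db))))
    tibble::tibble(
      participant_id = participant_id, eye = eye,
      # OS fields are recorded in their own (mirror-image) orientation
      x_deg = if (eye == "OS") -grid$x_deg else grid$x_deg,
      y_deg = grid$y_deg,
      sensitivity_db = sens)
  })
}

#' Simulate a full synthetic cohort with known latent truth
#'
#' Generates, for every participant: two GPS weeks (baseline and year 1,
#' the year-1 excursion rate multiplied by `irr_fall_on_excursions` for
#' fallers), 12 monthly falls calendars with injury marks, one paired-eye
#' visual field, and baseline covariates. The returned `truth` component
#' carries the planted latent parameters and is never an input to the
#' pipeline stages.
#'
#' @param scenario a [cohort_scenario()].
#' @param seed RNG seed; defaults to `scenario$seed`. The same
#'   (scenario, seed) always yields an identical bundle.
#' @return list of class `lifespacer_cohort` with components `gps`,
#'   `calendar`, `month_status`, `falls`, `vf`, `covariates`, `truth`
#'   (list: `participants`, `days`) and `scenario`.
#' @export
simulate_cohort <- function(scenario = cohort_scenario(),
                            seed = scenario$seed) {
  if (!inherits(scenario, "cohort_scenario")) {
    abort("`scenario` must be built with cohort_scenario()")
  }
  set.seed(seed)
  s <- scenario
  ids <- sprintf("P%04d", seq_len(s$n_participants))
  baseline_start <- as.Date("2014-03-03")
  year1_start <- baseline_start + 364
  parts <- vector("list", s$n_participants)
  gps <- list(); truth_days <- list()
  calendar <- list(); month_status <- list(); falls <- list(); vf <- list()
  for (i in seq_len(s$n_participants)) {
    id <- ids[i]
    home_lat <- s$home_centre_lat + runif(1, -s$home_spread_deg,
                                          s$home_spread_deg)
    home_lon <- s$home_centre_lon + runif(1, -s$home_spread_deg,
                                          s$home_spread_deg)
    faller_latent <- runif(1) < s$faller_fraction
    n_falls <- if (faller_latent) 1L + rpois(1, s$recurrent_falls_mean) else 0L
    fy <- simulate_falls_year(id, s$injurious_given_fall, n_falls = n_falls,
                              start = baseline_start - 2,
                              missing_month_prob = s$missing_month_prob)
    calendar[[i]] <- fy$calendar
    month_status[[i]] <- fy$month_status
    falls[[i]] <- fy$falls
    frailty <- rgamma(1, shape = s$excursion_rate_dispersion,
                      rate = s$excursion_rate_dispersion)
    rate_baseline <- s$base_daily_excursion_rate * frailty
    rate_year1 <- rate_baseline *
      ifelse(faller_latent, s$irr_fall_on_excursions, 1)
    wk_b <- simulate_gps_week(id, "baseline", home_lat, home_lon,
                              rate_baseline,
                              s$excursion_duration_log_mean,
                              s$excursion_duration_log_sd,
                              s$gps_noise_sd_m, s$missing_day_prob,
                              s$missing_minute_prob, baseline_start)
    wk_1 <- simulate_gps_week(id, "year1", home_lat, home_lon, rate_year1,
                              s$excursion_duration_log_mean,
                              s$excursion_duration_log_sd,
                              s$gps_noise_sd_m, s$missing_day_prob,
                              s$missing_minute_prob, year1_start)
    gps[[i]] <- dplyr::bind_rows(wk_b$gps, wk_1$gps)
    truth_days[[i]] <- dplyr::bind_rows(wk_b$truth, wk_1$truth)
    latent_db <- rnorm(1, s$vf_mean_db, s$vf_sd_db)
    vf[[i]] <- simulate_vf_pair(id, latent_db, s$vf_point_sd_db)
    parts[[i]] <- tibble::tibble(
      participant_id = id,
      home_lat = home_lat, home_lon = home_lon,
      faller_latent = faller_latent,
      n_falls_true = n_falls,
      n_injurious_true = sum(fy$falls$injurious),
      rate_baseline = rate_baseline, rate_year1 = rate_year1,
      vf_latent_db = latent_db,
      age = round(rnorm(1, s$age_mean, s$age_sd), 1),
      male = as.integer(runif(1) < s$male_prop),
      black = as.integer(runif(1) < s$black_prop),
      comorbid_gt1 = as.integer(runif(1) < s$comorbid_gt1_prop),
      polypharmacy = as.integer(runif(1) < s$polypharmacy_prop))
  }
  participants <- dplyr::bind_rows(parts)
  covariates <- participants[, c("participant_id", "age", "male", "black",
                                 "comorbid_gt1", "polypharmacy")]
  structure(
    list(gps = dplyr::bind_rows(gps),
         calendar = dplyr::bind_rows(calendar),
         month_status = dplyr::bind_rows(month_status),
         falls = dplyr::bind_rows(falls),
         vf = dplyr::bind_rows(vf),
         covariates = covariates,
         truth = list(participants = participants,
                      days = dplyr::bind_rows(truth_days)),
         scenario = scenario),
    class = "lifespacer_cohort")
}

#' Simulate analysis rows directly (for model calibration studies)
#'
#' Bypasses the GPS stages and draws analysis rows at the
#' participant-visit level: excursion totals are Poisson counts with a
#' shared gamma frailty per participant (marginally negative binomial,
#' exchangeably correlated across the two visits), exposure is valid days,
#' and fallers' final-visit rate is multiplied by `irr` (optionally
#' modified per severity stratum). Used by the Monte-Carlo calibration and
#' parameter-recovery checks of the inference stage.
#'
#' @param n_participants number of participants.
#' @param irr multiplicative fall effect on the final-visit rate.
#' @param base_rate baseline excursions/day.
#' @param frailty_shape gamma frailty shape (= rate; mean 1, variance
#'   1/shape). The marginal NB dispersion theta equals this shape.
#' @param faller_fraction probability of being a faller.
#' @param visits 1 (final visit only) or 2 (baseline + year 1).
#' @param irr_by_severity optional named multiplier on `irr` per severity
#'   level (e.g. `c(severe = 2)`).
#' @param seed optional seed.
#' @return tibble shaped like [build_analysis_rows()] output for the
#'   daily-excursions outcome.
#' @export
simulate_analysis_rows <- function(n_participants, irr = 1, base_rate = 2.5,
                                   frailty_shape = 2.5,
                                   faller_fraction = 0.453, visits = 2,
                                   irr_by_severity = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_participants
  faller <- runif(n) < faller_fraction
  frailty <- rgamma(n, shape = frailty_shape, rate = frailty_shape)
  severity <- factor(
    sample(c("mild", "moderate", "severe"), n, replace = TRUE,
           prob = c(0.511, 0.385, 0.104)),
    levels = c("mild", "moderate", "severe"))
  covs <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    faller = faller,
    age = round(rnorm(n, 70.1, 7), 1),
    male = as.integer(runif(n) < 0.505),
    black = as.integer(runif(n) < 0.281),
    comorbid_gt1 = as.integer(runif(n) < 0.63),
    polypharmacy = as.integer(runif(n) < 0.307),
    ivf_mean_db = rnorm(n, 27.5, 2.7),
    severity = severity)
  sev_mult <- rep(1, n)
  if (!is.null(irr_by_severity)) {
    for (lev in names(irr_by_severity)) {
      sev_mult[severity == lev] <- irr_by_severity[[lev]]
    }
  }
  rows <- purrr::map_dfr(seq_len(visits), function(v) {
    final <- v == visits
    days <- sample(4:7, n, replace = TRUE)
    rate <- base_rate * frailty *
      ifelse(final & faller, irr * sev_mult, 1)
    dplyr::mutate(covs,
                  visit = if (final) 2L else v, # the fall effect acts at the final visit
                  outcome = "daily_excursions",
                  total = rpois(n, days * rate),
                  n_valid_days = days,
                  log_exposure = log(days))
  })
  dplyr::select(rows, "participant_id", "visit", "outcome", "total",
                "n_valid_days", "log_exposure", "faller", "age", "male",
                "black", "comorbid_gt1", "polypharmacy", "ivf_mean_db",
                "severity")
}
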