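# GPS stage: distance, home anchoring, labeling, valid-day QC,
# segmentation and weekly summaries.

test_that("haversine distance matches closed forms and an independent oracle", {
  expect_identical(haversine_m(39, -76.5, 39, -76.5), 0)
  # one degree along a meridian: R * pi/180
  expect_equal(haversine_m(0, 0, 1, 0), 111194.93, tolerance = 1e-7)
  # short urban pair, frozen from an independent haversine implementation
  expect_equal(haversine_m(39.2904, -76.6122, 39.2904, -76.6110),
               103.27069, tolerance = 1e-6)
  # symmetry and non-negativity on random pairs; cross-check vs geosphere
  set.seed(11)
  a <- cbind(runif(50, -60, 60), runif(50, -179, 179))
  b <- cbind(runif(50, -60, 60), runif(50, -179, 179))
  d_ab <- haversine_m(a[, 1], a[, 2], b[, 1], b[, 2])
  expect_equal(d_ab, haversine_m(b[, 1], b[, 2], a[, 1], a[, 2]))
  expect_true(all(d_ab >= 0))
  d_geo <- geosphere::distHaversine(cbind(a[, 2], a[, 1]),
                                    cbind(b[, 2], b[, 1]), r = 6371000)
  expect_equal(d_ab, d_geo, tolerance = 1e-9)
  expect_error(haversine_m(91, 0, 0, 0), "lat")
})

night_trace <- function(lats, lons, participant = "p1",
                        visit = "baseline") {
  t0 <- as.numeric(as.POSIXct("2014-03-03 02:30:00", tz = "UTC"))
  tibble::tibble(participant_id = participant, visit = visit,
                 timestamp = as.POSIXct(t0 + seq_along(lats) * 60,
                                        origin = "1970-01-01", tz = "UTC"),
                 lat = lats, lon = lons)
}

test_that("home anchor is the componentwise median of night-window fixes", {
  same <- night_trace(rep(39, 5), rep(-76.5, 5))
  h <- estimate_home(same)
  expect_equal(h$home_lat, 39)
  expect_equal(h$home_lon, -76.5)

  odd <- night_trace(c(39.0000, 39.0001, 39.0002),
                     c(-76.5000, -76.5001, -76.5002))
  h <- estimate_home(odd)
  expect_equal(h$home_lat, 39.0001)
  expect_equal(h$home_lon, -76.5001)

  # fixes outside [02:00, 04:00) are ignored; none inside is an error
  t0 <- as.POSIXct("2014-03-03 12:00:00", tz = "UTC")
  daytime <- tibble::tibble(participant_id = "p9", visit = "baseline",
                            timestamp = t0 + (0:10) * 60, lat = 1, lon = 1)
  expect_error(estimate_home(daytime), "home unidentifiable.*p9")
})

test_that("home anchor recovers a jittered planted home within meters", {
  set.seed(21)
  hits <- vapply(1:60, function(i) {
    wk <- simulate_gps_week("p", "baseline", 39.29, -76.61, daily_rate = 2,
                            noise_sd_m = 10)
    h <- estimate_home(dedupe_fixes(wk$gps))
    haversine_m(h$home_lat, h$home_lon, 39.29, -76.61) < 5
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("home margin is boundary-inclusive at the configured radius", {
  home <- tibble::tibble(participant_id = "p1", visit = "baseline",
                         home_lat = 39, home_lon = -76.5,
                         n_night_fixes = 10L)
  fix <- function(lat) {
    tibble::tibble(participant_id = "p1", visit = "baseline",
                   timestamp = as.POSIXct("2014-03-03 10:00:00", tz = "UTC"),
                   lat = lat, lon = -76.5)
  }
  at_anchor <- classify_fixes(fix(39), home)
  at_50 <- classify_fixes(fix(39 + lat_offset_m(50)), home)
  at_60 <- classify_fixes(fix(39 + lat_offset_m(60)), home)
  expect_identical(at_anchor$label, "home")
  expect_identical(at_50$label, "home") # exactly on the boundary
  expect_identical(at_60$label, "away")
  expect_equal(at_50$dist_home_m, 50, tolerance = 1e-6)
})

test_that("away-minute count never increases when the radius grows", {
  set.seed(31)
  wk <- simulate_gps_week("p", "baseline", 39.29, -76.61, daily_rate = 3,
                          noise_sd_m = 40)
  gps <- dedupe_fixes(wk$gps)
  homes <- estimate_home(gps)
  away_at <- function(r) sum(classify_fixes(gps, homes, r)$label == "away")
  counts <- vapply(c(10, 30, 50, 100, 250), away_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("valid-day coverage threshold is inclusive at 80% of 960 minutes", {
  trace <- dplyr::bind_rows(
    window_day_trace(960, participant = "full"),
    window_day_trace(768, participant = "edge"),
    window_day_trace(767, participant = "below"))
  byid <- qc_valid_days(trace)
  expect_equal(byid$coverage[byid$participant_id == "full"], 1.0)
  expect_true(byid$valid[byid$participant_id == "full"])
  expect_equal(byid$coverage[byid$participant_id == "edge"], 0.8)
  expect_true(byid$valid[byid$participant_id == "edge"])
  expect_false(byid$valid[byid$participant_id == "below"])
  # night fixes exist but contribute nothing to window coverage
  expect_equal(byid$n_window_minutes[byid$participant_id == "below"], 767)
})

test_that("participants need at least the minimum number of valid days", {
  mk <- function(id, n_valid, n_days = 7) {
    tibble::tibble(participant_id = id, visit = "baseline",
                   date = as.Date("2014-03-03") + seq_len(n_days) - 1,
                   n_window_minutes = 960L, coverage = 1,
                   valid = seq_len(n_days) <= n_valid)
  }
  days <- dplyr::bind_rows(mk("none", 0), mk("two", 2), mk("all", 7))
  inc <- meets_min_valid_days(days, min_valid_days = 2)
  expect_identical(inc$included[inc$participant_id == "none"], FALSE)
  expect_identical(inc$included[inc$participant_id == "two"], TRUE)
  expect_identical(inc$included[inc$participant_id == "all"], TRUE)
})

test_that("segmentation reproduces crafted label-string examples", {
  seg <- function(labels, ...) {
    segment_excursions(labels_to_trace(labels), ...)$duration_min
  }
  expect_identical(seg(rep("H", 10)), integer(0))
  expect_identical(seg(c("H", "H", "A", "A", "A", "H")), 3L)
  expect_identical(seg(c("H", "A", "H", "A", "A", "H")), c(1L, 2L))
  # a missing minute between away minutes breaks the run unless bridged
  expect_identical(seg(c("A", "M", "A")), c(1L, 1L))
  expect_identical(seg(c("A", "M", "A"), gap_bridge_min = 1), 3L)
  expect_identical(seg(c("A", "M", "M", "A"), gap_bridge_min = 1), c(1L, 1L))
  # minimum-duration filter
  expect_identical(seg(c("H", "A", "H", "A", "A", "H"),
                       min_excursion_min = 2), 2L)
})

test_that("segmentation agrees exactly with the brute-force oracle", {
  set.seed(41)
  configs <- expand.grid(bridge = c(0, 1, 3), min_dur = c(1, 5))
  for (i in 1:400) {
    labels <- random_labels(sample(1:500, 1))
    cfg <- configs[sample(nrow(configs), 1), ]
    got <- segment_excursions(labels_to_trace(labels),
                              gap_bridge_min = cfg$bridge,
                              min_excursion_min = cfg$min_dur)
    want <- oracle_segment(labels, cfg$bridge, cfg$min_dur)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$duration_min, want$duration)
    # start minutes line up too (oracle positions are 1-based minutes)
    midnight <- as.numeric(as.POSIXct(as.Date("2014-03-03"), tz = "UTC"))
    expect_identical(
      as.integer((as.numeric(got$start) - midnight) / 60) + 1L,
      want$start)
  }
})

test_that("excursion durations conserve away plus bridged minutes", {
  set.seed(51)
  for (i in 1:100) {
    labels <- random_labels(sample(50:400, 1))
    bridge <- sample(0:3, 1)
    got <- segment_excursions(labels_to_trace(labels),
                              gap_bridge_min = bridge,
                              min_excursion_min = 1)
    # without bridging, total duration is exactly the away-minute count;
    # with bridging it exceeds it by exactly the bridged missing minutes,
    # which the oracle counts independently
    if (bridge == 0) {
      expect_identical(sum(got$duration_min), sum(labels == "A"))
    } else {
      want <- oracle_segment(labels, bridge, 1)
      in_run <- unlist(mapply(seq, want$start, want$end, SIMPLIFY = FALSE))
      bridged <- sum(labels[in_run] == "M")
      expect_identical(sum(got$duration_min), sum(labels == "A") + bridged)
    }
  }
})

test_that("weekly summaries average over valid days with the identity", {
  # 2 valid days, excursions 2 + 4 of 80 min each -> 3/day, 8h away, 4/3 h
  day1 <- as.Date("2014-03-03")
  excursions <- tibble::tibble(
    participant_id = "p1", visit = "baseline",
    date = rep(c(day1, day1 + 1), c(2, 4)),
    start = as.POSIXct(day1, tz = "UTC"), end = as.POSIXct(day1, tz = "UTC"),
    duration_min = rep(80L, 6))
  days <- tibble::tibble(participant_id = "p1", visit = "baseline",
                         date = c(day1, day1 + 1, day1 + 2),
                         n_window_minutes = c(960L, 960L, 100L),
                         coverage = c(1, 1, 100 / 960),
                         valid = c(TRUE, TRUE, FALSE))
  s <- summarize_excursions(excursions, days)
  expect_equal(s$n_valid_days, 2L)
  expect_equal(s$avg_daily_excursions, 3.0)
  expect_equal(s$avg_daily_time_away_h, 480 / 2 / 60)
  expect_equal(s$avg_time_per_excursion_h, 480 / 6 / 60)
  expect_equal(s$avg_daily_time_away_h,
               s$avg_daily_excursions * s$avg_time_per_excursion_h)
  expect_true(s$included)

  # zero excursions: rates are zero and time-per-excursion is undefined
  none <- summarize_excursions(excursions[0, ], days)
  expect_equal(none$avg_daily_excursions, 0)
  expect_equal(none$avg_daily_time_away_h, 0)
  expect_true(is.na(none$avg_time_per_excursion_h))
})

test_that("duplicate minute fixes are dropped with a warning, first kept", {
  t0 <- as.POSIXct("2014-03-03 10:00:30", tz = "UTC")
  gps <- tibble::tibble(
    participant_id = "p1", visit = "baseline",
    timestamp = c(t0, t0 + 10, t0 + 61), # two fixes inside minute one
    lat = c(39, 40, 39), lon = -76.5)
  expect_warning(clean <- dedupe_fixes(gps), "duplicate")
  expect_identical(nrow(clean), 2L)
  expect_equal(clean$lat[1], 39) # the first of the duplicates survives
  expect_identical(unname(as.numeric(clean$timestamp)) %% 60, c(0, 0))
})
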