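# NB IRR models, severity interaction, and the GEE engine.

summaries_fixture <- function() {
  tibble::tibble(
    participant_id = c("a", "a", "b", "b", "c", "c"),
    visit = rep(c("baseline", "year1"), 3),
    n_valid_days = c(3L, 3L, 4L, 4L, 5L, 5L),
    n_excursions = c(6L, 6L, 0L, 0L, 10L, 8L),
    away_minutes = c(300L, 360L, 0L, 0L, 700L, 650L),
    avg_daily_excursions = c(2, 2, 0, 0, 2, 1.6),
    avg_daily_time_away_h = c(5 / 3, 2, 0, 0, 7 / 3, 65 / 30),
    avg_time_per_excursion_h = c(5 / 6, 1, NA, NA, 7 / 6, 650 / 8 / 60),
    included = TRUE)
}

statuses_fixture <- function(ids = c("a", "b", "c")) {
  tibble::tibble(participant_id = ids,
                 n_falls = c(2L, 0L, 1L)[seq_along(ids)],
                 n_injurious = c(1L, 0L, 0L)[seq_along(ids)],
                 faller = c(TRUE, FALSE, TRUE)[seq_along(ids)],
                 recurrent_faller = c(TRUE, FALSE, FALSE)[seq_along(ids)],
                 injurious_faller = c(TRUE, FALSE, FALSE)[seq_along(ids)],
                 recurrent_injurious_faller = FALSE,
                 n_missing_months = 0L)
}

covariates_fixture <- function(ids = c("a", "b", "c")) {
  tibble::tibble(participant_id = ids, age = c(70, 65, 80)[seq_along(ids)],
                 male = c(1L, 0L, 1L)[seq_along(ids)],
                 black = c(0L, 1L, 0L)[seq_along(ids)],
                 comorbid_gt1 = c(1L, 0L, 0L)[seq_along(ids)],
                 polypharmacy = c(0L, 0L, 1L)[seq_along(ids)])
}

ivf_fixture <- function(ids = c("a", "b", "c")) {
  tibble::tibble(participant_id = ids,
                 ivf_mean_db = c(29, 25, 21)[seq_along(ids)],
                 severity = factor(c("mild", "moderate", "severe")[seq_along(ids)],
                                   levels = c("mild", "moderate", "severe")))
}

test_that("analysis rows encode totals with log-exposure offsets", {
  rows <- build_analysis_rows(summaries_fixture(), statuses_fixture(),
                              covariates_fixture(), ivf_fixture())
  a2 <- rows[rows$participant_id == "a" & rows$visit == 2, ]
  de <- a2[a2$outcome == "daily_excursions", ]
  expect_identical(de$total, 6L)
  expect_equal(de$log_exposure, log(3))
  ta <- a2[a2$outcome == "daily_time_away", ]
  expect_identical(ta$total, 360L)
  expect_equal(ta$log_exposure, log(3))
  tpe <- a2[a2$outcome == "time_per_excursion", ]
  expect_identical(tpe$total, 360L)
  expect_equal(tpe$log_exposure, log(6))
  # zero-excursion participants contribute no time-per-excursion rows
  expect_identical(nrow(rows[rows$participant_id == "b" &
                               rows$outcome == "time_per_excursion", ]), 0L)
  # 3 participants x 2 visits x 3 outcomes, minus b's 2 undefined rows
  expect_identical(nrow(rows), 16L)
})

test_that("unmatched identifiers are reported by name", {
  expect_error(
    build_analysis_rows(summaries_fixture(),
                        statuses_fixture(c("a", "b", "zz")),
                        covariates_fixture(), ivf_fixture()),
    "missing from a linked table.*c")
})

test_that("degenerate model inputs raise errors rather than fitting", {
  rows <- simulate_analysis_rows(100, seed = 31)
  rows$faller <- TRUE
  expect_error(fit_excursion_nb(rows, exposure = "faller"), "constant")
  rows2 <- simulate_analysis_rows(100, seed = 32)
  rows2$total <- 0L
  expect_error(fit_excursion_nb(rows2, exposure = "faller"), "all zero")
  rows3 <- simulate_analysis_rows(100, seed = 33)
  rows3$severity <- factor("mild", levels = levels(rows3$severity))
  expect_error(fit_excursion_nb_interaction(rows3, exposure = "faller"),
               "severity is constant")
})

test_that("the NB model recovers a planted IRR on one large cohort", {
  rows <- simulate_analysis_rows(2000, irr = 1.5, visits = 1, seed = 34)
  fit <- fit_excursion_nb(rows, exposure = "faller")
  expect_true(fit$converged)
  expect_gt(fit$result$irr, 1.35)
  expect_lt(fit$result$irr, 1.65)
  expect_true(fit$result$ci_low <= fit$result$irr &&
                fit$result$irr <= fit$result$ci_high)
  expect_lt(fit$result$p_value, 0.05)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "p.value") %in%
                    names(td)))
  expect_equal(td$estimate[td$term == "faller"], fit$result$irr)
  gl <- glance(fit)
  expect_identical(gl$nobs, 2000L)
})

test_that("rescaling the exposure leaves the IRR invariant", {
  rows <- simulate_analysis_rows(400, irr = 1.5, visits = 1, seed = 35)
  f1 <- fit_excursion_nb(rows, exposure = "faller")
  rows2 <- dplyr::mutate(rows, log_exposure = log_exposure + log(3))
  f2 <- fit_excursion_nb(rows2, exposure = "faller")
  expect_equal(f1$result$irr, f2$result$irr, tolerance = 1e-7)
  expect_equal(f1$result$p_value, f2$result$p_value, tolerance = 1e-6)
})

test_that("a strong severity-specific effect is flagged by the interaction", {
  rows <- simulate_analysis_rows(2500, irr = 1.2, visits = 1,
                                 irr_by_severity = c(severe = 2.5),
                                 seed = 36)
  fit <- fit_excursion_nb_interaction(rows, exposure = "faller")
  expect_lt(fit$interaction_p, 0.05)
  expect_identical(fit$interaction_df, 2L)
})

test_that("under no severity modification the interaction is rarely flagged", {
  set.seed(37)
  p <- vapply(1:30, function(i) {
    rows <- simulate_analysis_rows(400, irr = 1.2, visits = 1)
    fit_excursion_nb_interaction(rows, exposure = "faller")$interaction_p
  }, numeric(1))
  expect_true(all(p >= 0 & p <= 1))
  expect_lte(mean(p < 0.05), 0.2)
})

test_that("GEE with one row per cluster matches the GLM fixed point", {
  rows <- simulate_analysis_rows(350, irr = 1.4, visits = 1, seed = 38)
  form <- total ~ faller + age + male + offset(log_exposure)
  expect_warning(
    ge <- gee_count(form, rows, participant_id, theta = Inf),
    "independence")
  ctrl <- stats::glm.control(epsilon = 1e-14)
  gl <- glm(form, data = rows, family = poisson(), control = ctrl)
  expect_lt(max(abs(ge$coefficients - coef(gl)) / abs(coef(gl))), 1e-6)
  # same property for the NB2 variance function
  expect_warning(
    ge2 <- gee_count(form, rows, participant_id, theta = 2.5), "independence")
  gl2 <- glm(form, data = rows, family = MASS::negative.binomial(2.5),
             control = ctrl)
  expect_lt(max(abs(ge2$coefficients - coef(gl2)) / abs(coef(gl2))), 1e-6)
})

test_that("GEE estimates a positive working correlation for shared frailty", {
  rows <- simulate_analysis_rows(400, irr = 1, visits = 2, seed = 39)
  fit <- fit_excursion_gee(rows, exposure = "faller")
  expect_true(fit$converged)
  expect_gt(fit$engine$alpha, 0.3)
  expect_identical(fit$n_clusters, 400L)
  expect_identical(fit$n_obs, 800L)
})

test_that("the visit interaction is null-centred when rates do not change", {
  set.seed(40)
  z <- vapply(1:25, function(i) {
    rows <- simulate_analysis_rows(300, irr = 1, visits = 2)
    fit <- fit_excursion_gee(rows, exposure = "faller",
                             visit_interaction = TRUE)
    fit$result$estimate / fit$result$std.error
  }, numeric(1))
  expect_lt(mean(abs(z) > 3), 0.10)
  expect_lt(abs(mean(z)), 0.6)
})

test_that("the IRR grid and report table format cells as IRR (CI)", {
  grid <- tidyr::expand_grid(
    exposure = c("faller", "recurrent_faller", "injurious_faller",
                 "recurrent_injurious_faller"),
    outcome = c("daily_excursions", "daily_time_away",
                "time_per_excursion"),
    model = c("NB-univariate", "NB-multivariable"))
  fake <- dplyr::mutate(grid, irr = 1.16, ci_low = 0.85, ci_high = 1.57,
                        p_value = 0.36, n_obs = 192L, converged = TRUE)
  fake$irr[1] <- 1.164; fake$ci_low[1] <- 0.851; fake$ci_high[1] <- 1.5651
  fake$p_value[2] <- 0.05 # boundary significance is starred
  tab <- format_irr_table(fake)
  cells <- unlist(tab[, -1])
  expect_true("1.16 (0.85, 1.57)" %in% cells)
  expect_true(any(grepl("\\*$", cells)))
  expect_error(format_irr_table(fake[-3, ]), "missing model cells")
  expect_error(format_irr_table(fake[0, ]), "empty")
})
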