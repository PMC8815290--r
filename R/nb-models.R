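# Negative binomial IRR models of excursion parameters on fall status.
#
# The three weekly averages are encoded as integer totals with log-exposure
# offsets so that the NB likelihood is coherent and exp(coefficients) keep
# their incidence-rate-ratio reading:
#   daily excursions    -> total excursions,   offset log(valid days)
#   daily time away     -> total away minutes, offset log(valid days)
#   time per excursion  -> total away minutes, offset log(total excursions)
# Participants with zero excursions contribute no time-per-excursion row.

OUTCOME_KINDS <- c("daily_excursions", "daily_time_away", "time_per_excursion")
EXPOSURES <- c("faller", "recurrent_faller", "injurious_faller",
               "recurrent_injurious_faller")
ADJUSTMENT_COVARIATES <- c("age", "male", "black", "ivf_mean_db",
                           "comorbid_gt1", "polypharmacy")

#' Assemble model-ready analysis rows
#'
#' Joins excursion summaries, fall status, covariates, and the integrated
#' visual field into one long table with a row per
#' participant-visit-outcome. Only participant-visits that passed the
#' minimum-valid-days filter are kept; identifiers present in the
#' summaries but absent from the other tables raise an error naming them.
#'
#' @param summaries excursion summaries (see [summarize_excursions()]).
#' @param statuses fall status per participant
#'   (see [classify_fall_status()]).
#' @param covariates tibble with `participant_id`, `age`, `male`, `black`,
#'   `comorbid_gt1`, `polypharmacy`.
#' @param ivf per-participant IVF table (see [ivf_table()]).
#' @return tibble with columns `participant_id`, `visit` (1 = baseline,
#'   2 = year 1), `outcome`, `total`, `n_valid_days`, `log_exposure`, the
#'   four fall-status indicators, covariates, `ivf_mean_db`, `severity`.
#' @export
build_analysis_rows <- function(summaries, statuses, covariates, ivf) {
  included <- summaries[summaries$included, , drop = FALSE]
  for (tab in list(statuses = statuses, covariates = covariates, ivf = ivf)) {
    missing <- setdiff(included$participant_id, tab$participant_id)
    if (length(missing) > 0) {
      abort(paste0("participants missing from a linked table: ",
                   paste(sort(unique(missing)), collapse = ", ")))
    }
  }
  base <- included |>
    dplyr::mutate(visit = dplyr::case_match(.data$visit,
                                            "baseline" ~ 1L, "year1" ~ 2L,
                                            .default = NA_integer_)) |>
    dplyr::inner_join(
      statuses[, c("participant_id", EXPOSURES)], by = "participant_id") |>
    dplyr::inner_join(covariates, by = "participant_id") |>
    dplyr::inner_join(ivf[, c("participant_id", "ivf_mean_db", "severity")],
                      by = "participant_id")
  if (anyNA(base$visit)) abort("`visit` must be \"baseline\" or \"year1\"")
  rows <- dplyr::bind_rows(
    dplyr::mutate(base, outcome = "daily_excursions",
                  total = as.integer(.data$n_excursions),
                  log_exposure = log(.data$n_valid_days)),
    dplyr::mutate(base, outcome = "daily_time_away",
                  total = as.integer(round(.data$away_minutes)),
                  log_exposure = log(.data$n_valid_days)),
    base |>
      dplyr::filter(.data$n_excursions > 0) |>
      dplyr::mutate(outcome = "time_per_excursion",
                    total = as.integer(round(.data$away_minutes)),
                    log_exposure = log(.data$n_excursions))
  )
  dplyr::select(rows, "participant_id", "visit", "outcome", "total",
                "n_valid_days", "log_exposure", dplyr::all_of(EXPOSURES),
                "age", "male", "black", "comorbid_gt1", "polypharmacy",
                "ivf_mean_db", "severity")
}

check_rows <- function(rows, outcome, exposure) {
  rows <- rows[rows$outcome == outcome, , drop = FALSE]
  if (nrow(rows) == 0) abort(sprintf("no rows for outcome '%s'", outcome))
  if (!exposure %in% names(rows)) {
    abort(sprintf("exposure '%s' not found in rows", exposure))
  }
  if (dplyr::n_distinct(rows[[exposure]]) < 2) {
    abort(sprintf("exposure '%s' is constant; the contrast is unidentifiable",
                  exposure))
  }
  if (all(rows$total == 0)) abort("outcome totals are all zero")
  rows
}

nb_formula <- function(exposure, adjusted, extra = NULL) {
  terms <- c(exposure, if (adjusted) ADJUSTMENT_COVARIATES, extra)
  as.formula(paste("total ~", paste(terms, collapse = " + "),
                   "+ offset(log_exposure)"))
}

wald_summary <- function(fit, term, level = 0.95) {
  est <- coef(fit)[[term]]
  se <- sqrt(vcov(fit)[term, term])
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(term = term, estimate = est, std.error = se,
                 irr = exp(est),
                 ci_low = exp(est - z * se), ci_high = exp(est + z * se),
                 p_value = 2 * pnorm(-abs(est / se)))
}

#' Fit a negative binomial IRR model for one outcome and exposure
#'
#' Log-link NB2 regression (dispersion estimated by maximum likelihood via
#' [MASS::glm.nb()]) of the outcome total on a binary fall-status
#' exposure, with the log-exposure offset. `adjusted = TRUE` adds age,
#' sex, race, IVF mean sensitivity, comorbidity (> 1 illnesses) and
#' polypharmacy. The IRR is `exp` of the exposure coefficient with a Wald
#' 95% CI and two-sided p-value.
#'
#' @param rows analysis rows from [build_analysis_rows()] (the final-visit
#'   rows are selected with `visit`).
#' @param outcome one of `"daily_excursions"`, `"daily_time_away"`,
#'   `"time_per_excursion"`.
#' @param exposure one of the four fall-status indicators.
#' @param adjusted add the multivariable adjustment set?
#' @param visit which visit's rows to model (default 2, end of study).
#' @return object of class `lifespacer_nb`; see [tidy()] and [glance()].
#' @export
fit_excursion_nb <- function(rows, outcome = "daily_excursions",
                             exposure = "faller", adjusted = FALSE,
                             visit = 2) {
  rows <- check_rows(rows[rows$visit %in% visit, , drop = FALSE],
                     outcome, exposure)
  rows[[exposure]] <- as.integer(rows[[exposure]])
  fit <- suppressWarnings(
    MASS::glm.nb(nb_formula(exposure, adjusted), data = rows,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 200)))
  converged <- isTRUE(fit$converged) && !isTRUE(fit$th.warn == "iteration limit reached")
  structure(
    list(fit = fit, result = wald_summary(fit, exposure),
         outcome = outcome, exposure = exposure,
         model = if (adjusted) "NB-multivariable" else "NB-univariate",
         n_obs = nrow(rows), theta = fit$theta, converged = converged),
    class = "lifespacer_nb")
}

#' Fit the NB model with a visual-field-severity interaction
#'
#' Adds `exposure x severity` terms to the (multivariable, severity
#' main-effect) NB model and reports a joint Wald chi-square p-value for
#' the interaction, i.e. whether the fall-status IRR differs across the
#' glaucoma-severity spectrum.
#'
#' @inheritParams fit_excursion_nb
#' @return object of class `lifespacer_nb` with an extra
#'   `interaction_p` element (and `interaction_df`).
#' @export
fit_excursion_nb_interaction <- function(rows, outcome = "daily_excursions",
                                         exposure = "faller", visit = 2) {
  rows <- check_rows(rows[rows$visit %in% visit, , drop = FALSE],
                     outcome, exposure)
  if (dplyr::n_distinct(rows$severity) < 2) {
    abort("severity is constant; no interaction is estimable")
  }
  rows[[exposure]] <- as.integer(rows[[exposure]])
  rows$severity <- droplevels(rows$severity)
  covs <- setdiff(ADJUSTMENT_COVARIATES, "ivf_mean_db")
  form <- as.formula(paste(
    "total ~", exposure, "* severity +", paste(covs, collapse = " + "),
    "+ offset(log_exposure)"))
  fit <- suppressWarnings(
    MASS::glm.nb(form, data = rows,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 200)))
  int_terms <- grep(paste0("^", exposure, ":severity"), names(coef(fit)),
                    value = TRUE)
  b <- coef(fit)[int_terms]
  V <- vcov(fit)[int_terms, int_terms, drop = FALSE]
  w <- as.numeric(t(b) %*% solve(V, b))
  structure(
    list(fit = fit, result = wald_summary(fit, exposure),
         outcome = outcome, exposure = exposure, model = "NB-interaction",
         n_obs = nrow(rows), theta = fit$theta,
         converged = isTRUE(fit$converged),
         interaction_p = pchisq(w, df = length(int_terms),
                                lower.tail = FALSE),
         interaction_df = length(int_terms)),
    class = "lifespacer_nb")
}

#' @export
print.lifespacer_nb <- function(x, ...) {
  cat(sprintf("<%s> %s ~ %s (n = %d, theta = %.2f)\n", x$model, x$outcome,
              x$exposure, x$n_obs, x$theta))
  cat(sprintf("  IRR %.2f (%.2f, %.2f), p = %.3g\n", x$result$irr,
              x$result$ci_low, x$result$ci_high, x$result$p_value))
  if (!is.null(x$interaction_p)) {
    cat(sprintf("  interaction with severity: p = %.3g (df = %d)\n",
                x$interaction_p, x$interaction_df))
  }
  if (!x$converged) cat("  WARNING: model did not converge\n")
  invisible(x)
}

#' Tidy a fitted excursion model
#'
#' @param x a `lifespacer_nb` or `lifespacer_gee` object.
#' @param exponentiate report IRRs (`exp(coef)`) rather than log
#'   coefficients (default `TRUE`).
#' @param ... unused.
#' @return tibble with one row per model term: `term`, `estimate`,
#'   `std.error` (log scale), `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.lifespacer_nb <- function(x, exponentiate = TRUE, ...) {
  est <- unname(coef(x$fit))
  se <- unname(sqrt(diag(vcov(x$fit))))
  z <- qnorm(0.975)
  out <- tibble::tibble(term = names(coef(x$fit)), estimate = est,
                        std.error = se,
                        conf.low = est - z * se, conf.high = est + z * se,
                        p.value = 2 * pnorm(-abs(est / se)))
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(c("estimate", "conf.low",
                                              "conf.high"), exp))
  }
  out
}

#' @rdname tidy.lifespacer_nb
#' @export
glance.lifespacer_nb <- function(x, ...) {
  tibble::tibble(model = x$model, outcome = x$outcome,
                 exposure = x$exposure, nobs = x$n_obs, theta = x$theta,
                 converged = x$converged,
                 interaction.p.value = x$interaction_p %||% NA_real_)
}

#' Fit the full grid of IRR models
#'
#' Fits every fall-status exposure against every excursion outcome, both
#' univariate and multivariable: 4 x 3 x 2 = 24 models of the final-visit
#' parameters.
#'
#' @param rows analysis rows from [build_analysis_rows()].
#' @param visit which visit to model (default 2).
#' @return tibble with one row per model: `exposure`, `outcome`, `model`,
#'   `irr`, `ci_low`, `ci_high`, `p_value`, `n_obs`, `converged`.
#' @export
excursion_irr_table <- function(rows, visit = 2) {
  grid <- tidyr::expand_grid(exposure = EXPOSURES, outcome = OUTCOME_KINDS,
                             adjusted = c(FALSE, TRUE))
  purrr::pmap_dfr(grid, function(exposure, outcome, adjusted) {
    fit <- fit_excursion_nb(rows, outcome, exposure, adjusted, visit)
    dplyr::mutate(
      fit$result[, c("irr", "ci_low", "ci_high", "p_value")],
      exposure = exposure, outcome = outcome, model = fit$model,
      n_obs = fit$n_obs, converged = fit$converged, .before = 1)
  })
}

#' Format the IRR grid as a report table
#'
#' Renders each model as `"IRR (low, high)"` to two decimals, starred when
#' p <= 0.05, in a wide layout with one row per fall status and one column
#' per outcome-model pair. Errors if any of the 24 cells is missing.
#'
#' @param irr_table output of [excursion_irr_table()].
#' @return wide tibble of formatted cells.
#' @export
format_irr_table <- function(irr_table) {
  if (nrow(irr_table) == 0) abort("empty result set")
  expected <- tidyr::expand_grid(exposure = EXPOSURES,
                                 outcome = OUTCOME_KINDS,
                                 model = c("NB-univariate",
                                           "NB-multivariable"))
  gap <- dplyr::anti_join(expected, irr_table,
                          by = c("exposure", "outcome", "model"))
  if (nrow(gap) > 0) {
    abort(paste0("missing model cells: ",
                 paste(gap$exposure, gap$outcome, gap$model, sep = "/",
                       collapse = ", ")))
  }
  irr_table |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f, %.2f)%s", .data$irr,
                                 .data$ci_low, .data$ci_high,
                                 ifelse(.data$p_value <= 0.05, " *", ""))) |>
    dplyr::select("exposure", "outcome", "model", "cell") |>
    tidyr::pivot_wider(names_from = c("outcome", "model"),
                       values_from = "cell")
}
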