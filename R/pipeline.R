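# End-to-end orchestration: simulate (or ingest) -> excursions -> falls ->
# IVF -> models -> cohort report, deterministic under a fixed seed.

#' Pipeline configuration
#'
#' All analysis thresholds in one validated list. Defaults are the study
#' values: 50-m home margin, 80% coverage of 06:00-22:00 for a valid day,
#' 2 valid days minimum, 02:00-04:00 night window for home anchoring, and
#' severity cuts at 28/23 dB of IVF mean sensitivity.
#'
#' @param radius_m home-margin radius (m).
#' @param valid_fraction minimum day-window coverage for a valid day.
#' @param min_valid_days minimum valid days per participant-week.
#' @param gap_bridge_min missing-minute bridge for segmentation (minutes).
#' @param min_excursion_min minimum excursion duration (minutes).
#' @param night_window,day_window hour windows (half-open).
#' @param severity_cuts named dB cuts, `mild` and `severe`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(radius_m = 50, valid_fraction = 0.8,
                            min_valid_days = 2, gap_bridge_min = 0,
                            min_excursion_min = 1, night_window = c(2, 4),
                            day_window = c(6, 22),
                            severity_cuts = c(mild = 28, severe = 23)) {
  if (!is.numeric(radius_m) || radius_m <= 0) {
    abort("`radius_m` must be > 0")
  }
  assert_proportion(valid_fraction, "valid_fraction")
  if (min_valid_days < 1) abort("`min_valid_days` must be >= 1")
  assert_nonnegative(gap_bridge_min, "gap_bridge_min")
  if (min_excursion_min < 1) abort("`min_excursion_min` must be >= 1")
  if (severity_cuts[["mild"]] <= severity_cuts[["severe"]]) {
    abort("severity cut `mild` must exceed `severe`")
  }
  structure(mget(names(formals(pipeline_config))),
            class = "pipeline_config")
}

median_iqr <- function(x) {
  x <- x[!is.na(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3], n = length(x))
}

#' Cohort report: fall status, severity, and excursion parameters
#'
#' Mirrors the structure of a cohort descriptive table: fall-status counts
#' and percentages, IVF severity distribution, and medians (IQR, type-7
#' quantiles) of the three final-visit excursion parameters by faller
#' status.
#'
#' @param summaries excursion summaries.
#' @param statuses fall-status table.
#' @param ivf per-participant IVF table.
#' @param irr_table optional output of [excursion_irr_table()].
#' @return list of class `lifespacer_report` with components
#'   `fall_status`, `severity`, `excursions_by_fall_status` and (when
#'   supplied) `irr_cells`.
#' @export
cohort_report <- function(summaries, statuses, ivf, irr_table = NULL) {
  severity <- ivf |>
    dplyr::count(.data$severity, .drop = FALSE) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1))
  exc <- summaries |>
    dplyr::filter(.data$included, .data$visit == "year1") |>
    dplyr::inner_join(statuses[, c("participant_id", "faller")],
                      by = "participant_id") |>
    tidyr::pivot_longer(c("avg_daily_excursions", "avg_daily_time_away_h",
                          "avg_time_per_excursion_h"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$faller, .data$parameter) |>
    dplyr::reframe(median_iqr(.data$value))
  structure(
    list(fall_status = cohort_fall_table(statuses),
         severity = severity,
         excursions_by_fall_status = exc,
         irr_cells = if (!is.null(irr_table)) format_irr_table(irr_table)),
    class = "lifespacer_report")
}

#' @export
print.lifespacer_report <- function(x, ...) {
  cat("Fall status (counts, % round-half-up):\n")
  print(x$fall_status)
  cat("\nIVF severity distribution:\n")
  print(x$severity)
  cat("\nFinal-visit excursion parameters by faller status (median, IQR):\n")
  print(x$excursions_by_fall_status, n = Inf)
  if (!is.null(x$irr_cells)) {
    cat("\nIRR (95% CI) grid, * p <= 0.05:\n")
    print(x$irr_cells, width = Inf)
  }
  invisible(x)
}

#' Run the full pipeline on a cohort
#'
#' Executes every stage on a supplied cohort bundle (or a freshly
#' simulated one): excursion quantification, fall-status classification,
#' IVF staging, the 24-model NB IRR grid, GEE models across visits (with
#' and without the visit x fall-status interaction for every
#' outcome-exposure pair), and the cohort report. Deterministic for a
#' fixed (cohort or scenario, seed, config).
#'
#' @param cohort a `lifespacer_cohort` bundle (list with `gps`,
#'   `calendar`, `month_status`, `falls`, `vf`, `covariates`); when `NULL`
#'   one is simulated from `scenario`.
#' @param scenario scenario for simulation when `cohort` is `NULL`.
#' @param seed seed for the simulation.
#' @param config a [pipeline_config()].
#' @return list of class `lifespacer_run`: stage outputs (`excursions`,
#'   `fall_status`, `ivf`, `rows`), model tables (`irr_table`,
#'   `gee_table`), `report`, and a `manifest` of config, seed and
#'   per-stage row counts.
#' @export
run_pipeline <- function(cohort = NULL, scenario = cohort_scenario(),
                         seed = scenario$seed,
                         config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be built with pipeline_config()")
  }
  if (is.null(cohort)) cohort <- simulate_cohort(scenario, seed)
  exc <- excursion_summary(
    cohort$gps, radius_m = config$radius_m,
    valid_fraction = config$valid_fraction,
    min_valid_days = config$min_valid_days,
    gap_bridge_min = config$gap_bridge_min,
    min_excursion_min = config$min_excursion_min,
    night_window = config$night_window, day_window = config$day_window)
  months <- parse_calendars(cohort$calendar, cohort$month_status)
  statuses <- classify_fall_status(cohort$falls, months)
  ivf <- ivf_table(cohort$vf, config$severity_cuts)
  rows <- build_analysis_rows(exc$summary, statuses, cohort$covariates, ivf)
  irr_table <- excursion_irr_table(rows)
  gee_grid <- tidyr::expand_grid(outcome = OUTCOME_KINDS,
                                 exposure = EXPOSURES,
                                 interaction = c(FALSE, TRUE))
  gee_table <- purrr::pmap_dfr(gee_grid, function(outcome, exposure,
                                                  interaction) {
    fit <- fit_excursion_gee(rows, outcome, exposure, adjusted = TRUE,
                             visit_interaction = interaction)
    dplyr::mutate(fit$result, outcome = outcome, exposure = exposure,
                  visit_interaction = interaction,
                  converged = fit$converged, .before = 1)
  })
  report <- cohort_report(exc$summary, statuses, ivf, irr_table)
  manifest <- list(
    seed = seed,
    config = unclass(config),
    n_participants = dplyr::n_distinct(cohort$covariates$participant_id),
    n_gps_fixes = nrow(cohort$gps),
    n_excursions = nrow(exc$excursions),
    n_included_weeks = sum(exc$summary$included),
    n_analysis_rows = nrow(rows),
    n_models = nrow(irr_table) + nrow(gee_table))
  structure(
    list(cohort = cohort, excursions = exc, fall_status = statuses,
         ivf = ivf, rows = rows, irr_table = irr_table,
         gee_table = gee_table, report = report, manifest = manifest),
    class = "lifespacer_run")
}

#' @export
print.lifespacer_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<lifespacer_run> %d participants, %d GPS fixes, ",
                     "%d excursions, %d analysis rows, %d models\n"),
              m$n_participants, m$n_gps_fixes, m$n_excursions,
              m$n_analysis_rows, m$n_models))
  print(x$report)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes the stage tables as TSV, the report blocks and manifest as JSON.
#'
#' @param run a `lifespacer_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  tsv(run$excursions$summary, "excursion_summary.tsv")
  tsv(run$excursions$day_records, "day_records.tsv")
  tsv(run$fall_status, "fall_status.tsv")
  tsv(run$ivf, "ivf.tsv")
  tsv(run$rows, "analysis_rows.tsv")
  tsv(run$irr_table, "irr_table.tsv")
  tsv(run$gee_table, "gee_table.tsv")
  jsonlite::write_json(
    list(fall_status = run$report$fall_status,
         severity = run$report$severity,
         excursions_by_fall_status = run$report$excursions_by_fall_status,
         manifest = run$manifest),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
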