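# Prospective falls ascertainment: monthly falls calendars, injury
# follow-up, and the four binary fall-status classifications.

#' Parse monthly falls calendars
#'
#' Combines the day-level calendar (`participant_id`, `date`, `fell`) with
#' the month return-status table (`participant_id`, `month`, `returned`).
#' Months never returned within the collectibility horizon are treated as
#' missing: their day flags are discarded and they contribute nothing to
#' fall counts.
#'
#' @param calendar tibble with columns `participant_id`, `date` (Date),
#'   `fell` (0/1).
#' @param month_status optional tibble with columns `participant_id`,
#'   `month` (`"YYYY-MM"` character), `returned` (0/1). When `NULL`, every
#'   month appearing in `calendar` is assumed returned.
#' @return tibble with one row per participant-month: `month`, `status`
#'   (`"returned"`/`"missing"`), `n_fall_days`.
#' @export
parse_calendars <- function(calendar, month_status = NULL) {
  assert_columns(calendar, c("participant_id", "date", "fell"),
                 "calendar table")
  calendar <- dplyr::mutate(calendar, month = format(.data$date, "%Y-%m"))
  if (is.null(month_status)) {
    month_status <- calendar |>
      dplyr::distinct(.data$participant_id, .data$month) |>
      dplyr::mutate(returned = 1L)
  }
  assert_columns(month_status, c("participant_id", "month", "returned"),
                 "month-status table")
  if (anyDuplicated(month_status[c("participant_id", "month")])) {
    abort("month-status table has duplicate participant-month rows")
  }
  counts <- calendar |>
    dplyr::group_by(.data$participant_id, .data$month) |>
    dplyr::summarise(n_fall_days = sum(.data$fell > 0), .groups = "drop")
  month_status |>
    dplyr::left_join(counts, by = c("participant_id", "month")) |>
    dplyr::mutate(
      status = dplyr::if_else(.data$returned > 0, "returned", "missing"),
      n_fall_days = dplyr::if_else(.data$status == "returned",
                                   dplyr::coalesce(.data$n_fall_days, 0L),
                                   NA_integer_)
    ) |>
    dplyr::select("participant_id", "month", "status", "n_fall_days") |>
    dplyr::arrange(.data$participant_id, .data$month)
}

#' Classify fall status over the follow-up year
#'
#' From dated fall events (with the injury flag from the falls follow-up
#' interview) and the parsed calendar months, derives per participant:
#' faller (>= 1 fall), recurrent faller (> 1 fall), injurious faller (>= 1
#' injurious fall) and recurrent injurious faller (> 1 injurious fall).
#' Falls in months whose calendar was never returned are not counted;
#' status is computed from observed months only and `n_missing_months` is
#' reported so sensitivity analyses remain possible.
#'
#' @param falls tibble with columns `participant_id`, `date` (Date),
#'   `injurious` (0/1). May have zero rows.
#' @param months parsed calendar months from [parse_calendars()].
#' @return tibble with one row per participant: `n_falls`, `n_injurious`,
#'   `faller`, `recurrent_faller`, `injurious_faller`,
#'   `recurrent_injurious_faller`, `n_missing_months`.
#' @export
classify_fall_status <- function(falls, months) {
  assert_columns(falls, c("participant_id", "date", "injurious"),
                 "falls table")
  observed <- months[months$status == "returned", c("participant_id", "month")]
  falls <- falls |>
    dplyr::mutate(month = format(.data$date, "%Y-%m")) |>
    dplyr::semi_join(observed, by = c("participant_id", "month"))
  counts <- falls |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_falls = dplyr::n(),
                     n_injurious = sum(.data$injurious > 0),
                     .groups = "drop")
  months |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_missing_months = sum(.data$status == "missing"),
                     .groups = "drop") |>
    dplyr::left_join(counts, by = "participant_id") |>
    dplyr::mutate(
      n_falls = dplyr::coalesce(.data$n_falls, 0L),
      n_injurious = dplyr::coalesce(.data$n_injurious, 0L),
      faller = .data$n_falls >= 1,
      recurrent_faller = .data$n_falls >= 2,
      injurious_faller = .data$n_injurious >= 1,
      recurrent_injurious_faller = .data$n_injurious >= 2
    ) |>
    dplyr::select("participant_id", "n_falls", "n_injurious", "faller",
                  "recurrent_faller", "injurious_faller",
                  "recurrent_injurious_faller", "n_missing_months")
}

#' Cohort fall-status summary table
#'
#' Counts and percentages (one decimal, round-half-up) of each fall-status
#' class, over the whole cohort and -- for the recurrent/injurious classes
#' -- additionally over fallers only.
#'
#' @param statuses output of [classify_fall_status()].
#' @return tibble with columns `status`, `scope`
#'   (`"cohort"`/`"fallers"`), `n`, `denominator`, `pct`.
#' @export
cohort_fall_table <- function(statuses) {
  if (nrow(statuses) == 0) abort("no participants in `statuses`")
  n_total <- nrow(statuses)
  n_fallers <- sum(statuses$faller)
  flags <- c(faller = "faller", recurrent_faller = "recurrent_faller",
             injurious_faller = "injurious_faller",
             recurrent_injurious_faller = "recurrent_injurious_faller")
  cohort_rows <- purrr::map(names(flags), function(f) {
    tibble::tibble(status = f, scope = "cohort", n = sum(statuses[[f]]),
                   denominator = n_total)
  })
  faller_rows <- purrr::map(
    setdiff(names(flags), "faller"), function(f) {
      tibble::tibble(status = f, scope = "fallers", n = sum(statuses[[f]]),
                     denominator = n_fallers)
    })
  dplyr::bind_rows(cohort_rows, faller_rows) |>
    dplyr::mutate(pct = ifelse(.data$denominator > 0,
                               round_half_up(100 * .data$n / .data$denominator, 1),
                               NA_real_))
}
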