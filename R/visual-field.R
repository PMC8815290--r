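# Integrated visual field (IVF): pointwise-max binocular combination of
# paired-eye 24-2 sensitivities, mean sensitivity on the linear (1/Lambert)
# scale, and Hodapp-Parrish-Anderson-derived severity staging.

#' Canonical 24-2 test-point grid (right-eye orientation)
#'
#' The 54 locations of the Humphrey 24-2 pattern in degrees of visual
#' field, right-eye (OD) orientation: x positive temporal... i.e. the
#' physiologic blind spot sits at (15, +/-3). Left-eye (OS) fields are
#' recorded mirror-imaged; [integrate_fields()] maps them onto this grid by
#' negating x.
#'
#' @return tibble with columns `x_deg`, `y_deg`, `blind_spot` (logical,
#'   TRUE for the two blind-spot locations).
#' @export
vf_grid_24_2 <- function() {
  rows <- list(
    `21` = c(-9, -3, 3, 9),
    `15` = c(-15, -9, -3, 3, 9, 15),
    `9`  = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `3`  = c(-27, -21, -15, -9, -3, 3, 9, 15, 21)
  )
  grid <- purrr::map2_dfr(
    rep(as.numeric(names(rows)), each = 1),
    rows,
    function(y, xs) tibble::tibble(x_deg = xs, y_deg = y))
  grid <- dplyr::bind_rows(grid,
                           dplyr::mutate(grid, y_deg = -.data$y_deg))
  dplyr::mutate(grid,
                blind_spot = .data$x_deg == 15 & abs(.data$y_deg) == 3)
}

#' Decibel to linear (raw) sensitivity
#'
#' Differential light sensitivity in dB is `10 * log10` of the linear
#' sensitivity (1/Lambert convention), so the inverse is `10^(dB/10)`.
#'
#' @param db sensitivity in decibels.
#' @return linear sensitivity.
#' @export
db_to_linear <- function(db) 10^(db / 10)

#' Linear (raw) sensitivity to decibels
#' @param s linear sensitivity (> 0).
#' @return sensitivity in decibels.
#' @export
linear_to_db <- function(s) 10 * log10(s)

#' Mean sensitivity of a field on the linear scale
#'
#' Point sensitivities are converted to linear units, averaged, and the
#' mean is transformed back to dB: `10 * log10(mean(10^(dB/10)))`. By
#' Jensen's inequality this is at least the arithmetic mean of the dB
#' values.
#'
#' @param db numeric vector of point sensitivities in dB.
#' @return mean sensitivity in dB (length 1).
#' @export
#' @examples
#' mean_sensitivity_db(c(30, 20)) # 27.404 dB, not 25
mean_sensitivity_db <- function(db) {
  if (length(db) == 0 || any(!is.finite(db))) {
    abort("`db` must be a non-empty vector of finite sensitivities")
  }
  linear_to_db(mean(db_to_linear(db)))
}

#' Glaucoma severity from IVF mean sensitivity
#'
#' Hodapp-Parrish-Anderson-derived cuts on the integrated-field mean
#' sensitivity: none-to-mild damage at >= 28 dB, severe at <= 23 dB,
#' moderate strictly in between.
#'
#' @param mean_db IVF mean sensitivity in dB (vectorized).
#' @param cuts named numeric, `mild` and `severe` boundaries in dB.
#' @return factor with levels `mild`, `moderate`, `severe`.
#' @export
classify_severity <- function(mean_db, cuts = c(mild = 28, severe = 23)) {
  if (any(!is.finite(mean_db))) abort("`mean_db` must be finite")
  factor(ifelse(mean_db >= cuts[["mild"]], "mild",
                ifelse(mean_db <= cuts[["severe"]], "severe", "moderate")),
         levels = c("mild", "moderate", "severe"))
}

#' Integrate paired-eye visual fields pointwise
#'
#' Builds the binocular integrated visual field: OS points are mirrored to
#' OD orientation (`x -> -x`), matched to the spatially corresponding OD
#' points, and the maximum sensitivity of each pair is taken. The two
#' blind-spot locations are excluded, leaving 52 points per participant.
#'
#' @param vf tibble with columns `participant_id`, `eye` (`"OD"`/`"OS"`),
#'   `x_deg`, `y_deg`, `sensitivity_db`, each eye on the canonical 24-2
#'   grid in its own orientation.
#' @return tibble with one row per participant and non-blind-spot grid
#'   location: `x_deg`, `y_deg` (OD orientation), `sensitivity_db`.
#' @export
integrate_fields <- function(vf) {
  assert_columns(vf, c("participant_id", "eye", "x_deg", "y_deg",
                       "sensitivity_db"), "visual-field table")
  if (!all(vf$eye %in% c("OD", "OS"))) {
    abort("`eye` must be \"OD\" or \"OS\"")
  }
  if (any(vf$sensitivity_db < 0)) abort("sensitivities must be >= 0 dB")
  grid <- vf_grid_24_2()
  oriented <- vf |>
    dplyr::mutate(x_deg = ifelse(.data$eye == "OS", -.data$x_deg, .data$x_deg))
  check <- oriented |>
    dplyr::distinct(.data$participant_id, .data$eye, .data$x_deg, .data$y_deg) |>
    dplyr::count(.data$participant_id, .data$eye, name = "n_points")
  bad <- check[check$n_points < nrow(grid), , drop = FALSE]
  both <- tidyr::pivot_wider(check, names_from = "eye",
                             values_from = "n_points")
  if (!all(c("OD", "OS") %in% names(both)) ||
      anyNA(both$OD) || anyNA(both$OS)) {
    abort("every participant must have both an OD and an OS field")
  }
  if (nrow(bad) > 0) {
    detail <- oriented |>
      dplyr::semi_join(bad, by = c("participant_id", "eye")) |>
      dplyr::group_by(.data$participant_id, .data$eye) |>
      dplyr::summarise(
        missing = paste(
          setdiff(paste(grid$x_deg, grid$y_deg, sep = ","),
                  paste(.data$x_deg, .data$y_deg, sep = ",")),
          collapse = "; "),
        .groups = "drop")
    abort(paste0("incomplete 24-2 grid; missing locations (x,y in OD ",
                 "orientation): ",
                 paste(detail$participant_id, detail$eye, detail$missing,
                       sep = " ", collapse = " | ")))
  }
  keep <- grid[!grid$blind_spot, c("x_deg", "y_deg")]
  oriented |>
    dplyr::inner_join(keep, by = c("x_deg", "y_deg")) |>
    dplyr::group_by(.data$participant_id, .data$x_deg, .data$y_deg) |>
    dplyr::summarise(sensitivity_db = max(.data$sensitivity_db),
                     .groups = "drop")
}

#' Per-participant IVF mean sensitivity and severity
#'
#' Convenience driver: [integrate_fields()], then the linear-scale mean
#' sensitivity and severity class per participant.
#'
#' @inheritParams integrate_fields
#' @inheritParams classify_severity
#' @return tibble with one row per participant: `ivf_mean_db`, `severity`.
#' @export
ivf_table <- function(vf, cuts = c(mild = 28, severe = 23)) {
  integrate_fields(vf) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(ivf_mean_db = mean_sensitivity_db(.data$sensitivity_db),
                     .groups = "drop") |>
    dplyr::mutate(severity = classify_severity(.data$ivf_mean_db, cuts))
}
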