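# Shared helpers: rounding, timestamp arithmetic, input validation.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; cohort tables here follow the
#' round-half-up convention common in clinical reporting (45.25 -> 45.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 19.79), 0)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Minute-of-day (0..1439) and calendar date for POSIXct timestamps.
# All timestamps in the package live in a single fixed clock (stored as UTC,
# interpreted as the study-site local time); there is no DST handling.
minute_of_day <- function(timestamp) {
  secs <- as.numeric(timestamp)
  as.integer((secs %% 86400) %/% 60)
}

date_of <- function(timestamp) {
  as.Date(floor(as.numeric(timestamp) / 86400), origin = "1970-01-01")
}

# Absolute minute index since epoch; used to detect duplicate fixes and gaps.
minute_index <- function(timestamp) {
  floor(as.numeric(timestamp) / 60)
}

# Truncate (never round) timestamps to the whole minute.
truncate_to_minute <- function(timestamp) {
  as.POSIXct(floor(as.numeric(timestamp) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1], got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number", name))
  }
  invisible(x)
}

assert_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    abort("coordinates must be finite with lat in [-90, 90] and lon in [-180, 180]")
  }
  invisible(NULL)
}
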