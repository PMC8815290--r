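# Readers for the plain-text input dialects: GPS CSV/GPX, falls calendar
# CSV, injury CSV, and visual-field CSV. Timestamps are interpreted in a
# single fixed study-site clock (stored as UTC; no DST).

parse_timestamp <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) abort("unparseable timestamp(s) in GPS input")
  ts
}

#' Read a GPS fix table from CSV
#'
#' Expects a header row with columns
#' `participant_id,visit,timestamp,lat,lon`; `timestamp` ISO-8601 in the
#' study-site local clock. Timestamps are truncated to the minute.
#'
#' @param path CSV file path.
#' @return GPS tibble ready for [excursion_summary()].
#' @export
read_gps_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("participant_id", "visit", "timestamp", "lat", "lon"),
                 "GPS CSV")
  tibble::tibble(
    participant_id = as.character(df$participant_id),
    visit = as.character(df$visit),
    timestamp = truncate_to_minute(parse_timestamp(df$timestamp)),
    lat = as.numeric(df$lat), lon = as.numeric(df$lon))
}

#' Read a GPX 1.1 track as GPS fixes
#'
#' Maps every `<trkpt>` (lat/lon attributes plus `<time>`) to one fix,
#' truncating timestamps to the minute.
#'
#' @param path GPX file path.
#' @param participant_id,visit identifiers to attach to the fixes.
#' @return GPS tibble.
#' @export
read_gps_gpx <- function(path, participant_id, visit) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    abort("reading GPX requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0) abort("no <trkpt> elements found in GPX file")
  tibble::tibble(
    participant_id = participant_id, visit = visit,
    timestamp = truncate_to_minute(
      as.POSIXct(xml2::xml_text(xml2::xml_find_first(pts, "./time")),
                 tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon")))
}

#' Read falls calendar, month-status and injury CSV files
#'
#' Dialects: calendar `participant_id,date,fell` (0/1 per day);
#' month status `participant_id,month,returned` (`YYYY-MM`, 0/1);
#' injuries `participant_id,fall_date,injurious` (0/1).
#'
#' @param calendar_path,month_status_path,injury_path file paths;
#'   `month_status_path` may be `NULL`.
#' @return list with `calendar`, `month_status`, `falls` tibbles.
#' @export
read_falls_csv <- function(calendar_path, injury_path,
                           month_status_path = NULL) {
  cal <- read.csv(calendar_path, stringsAsFactors = FALSE)
  assert_columns(cal, c("participant_id", "date", "fell"), "calendar CSV")
  cal <- tibble::tibble(participant_id = as.character(cal$participant_id),
                        date = as.Date(cal$date),
                        fell = as.integer(cal$fell))
  ms <- NULL
  if (!is.null(month_status_path)) {
    ms <- read.csv(month_status_path, stringsAsFactors = FALSE)
    assert_columns(ms, c("participant_id", "month", "returned"),
                   "month-status CSV")
    ms <- tibble::tibble(participant_id = as.character(ms$participant_id),
                         month = as.character(ms$month),
                         returned = as.integer(ms$returned))
  }
  inj <- read.csv(injury_path, stringsAsFactors = FALSE)
  assert_columns(inj, c("participant_id", "fall_date", "injurious"),
                 "injury CSV")
  falls <- tibble::tibble(participant_id = as.character(inj$participant_id),
                          date = as.Date(inj$fall_date),
                          injurious = as.integer(inj$injurious))
  list(calendar = cal, month_status = ms, falls = falls)
}

#' Read a per-eye visual field CSV
#'
#' Expects `participant_id,eye,x_deg,y_deg,sensitivity_db` with each eye
#' in its own orientation on the 24-2 grid.
#'
#' @param path CSV file path.
#' @return VF tibble ready for [integrate_fields()].
#' @export
read_vf_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("participant_id", "eye", "x_deg", "y_deg",
                       "sensitivity_db"), "VF CSV")
  tibble::tibble(participant_id = as.character(df$participant_id),
                 eye = as.character(df$eye),
                 x_deg = as.numeric(df$x_deg),
                 y_deg = as.numeric(df$y_deg),
                 sensitivity_db = as.numeric(df$sensitivity_db))
}

#' Write a simulated cohort bundle to CSV files
#'
#' Writes the same dialects the readers above consume, plus the latent
#' truth as JSON (kept separate from the pipeline inputs).
#'
#' @param cohort a `lifespacer_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  gps <- dplyr::mutate(cohort$gps,
                       timestamp = format(.data$timestamp,
                                          "%Y-%m-%dT%H:%M:%S"))
  wr(gps, "gps.csv")
  wr(cohort$calendar, "calendar.csv")
  wr(cohort$month_status, "month_status.csv")
  wr(dplyr::rename(cohort$falls, fall_date = "date"), "injuries.csv")
  wr(cohort$vf, "vf.csv")
  wr(cohort$covariates, "covariates.csv")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
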