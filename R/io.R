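# Plain-CSV readers and writers for the pipeline's interchange formats.

#' Read an event-stream CSV
#'
#' Expected columns: \code{patient_id}, \code{timestamp} (ISO-8601 local
#' time), \code{event_type}.
#'
#' @param path file path.
#' @param tz timezone of the timestamps.
#' @return data.frame ready for [bin_events()].
#' @export
read_events_csv <- function(path, tz = "UTC") {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev$timestamp <- as.POSIXct(ev$timestamp, tz = tz,
                             tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                            "%Y-%m-%dT%H:%M:%OS"))
  ev
}

#' Read a long survey-response CSV
#'
#' Expected columns: \code{patient_id}, \code{date}, \code{item_id},
#' \code{response}.
#'
#' @param path file path.
#' @return data.frame ready for [score_surveys()].
#' @export
read_surveys_csv <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  s$date <- as.Date(s$date)
  s
}

#' Read a demographics CSV
#'
#' @param path file path.
#' @return data.frame with one row per patient.
#' @export
read_demographics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write daily activity to CSV
#'
#' Expands the 96-bin matrix column into columns \code{b0..b95}.
#'
#' @param activity output of [bin_events()].
#' @param path file path.
#' @export
write_activity_csv <- function(activity, path) {
  m <- activity$bins
  colnames(m) <- paste0("b", 0:95)
  out <- cbind(activity[c("patient_id", "date")], as.data.frame(m),
               activity[c("unique_active_hours", "adequate")])
  utils::write.csv(out, path, row.names = FALSE)
}

#' Write a simulated cohort to CSV files
#'
#' Writes \code{events.csv}, \code{surveys.csv}, \code{demographics.csv}
#' and \code{truth.csv} into a directory, with ISO-8601 timestamps.
#'
#' @param cohort output of [simulate_cohort()] (or of [simulate_events()],
#'   in which case only events/demographics/truth are written).
#' @param dir output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- cohort$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%d %H:%M:%OS3", tz = "UTC")
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(cohort$demographics,
                   file.path(dir, "demographics.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$surveys)) {
    utils::write.csv(cohort$surveys, file.path(dir, "surveys.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Write daily measures to CSV
#'
#' @param measures output of [daily_measures()].
#' @param path file path.
#' @export
write_measures_csv <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE)
}
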