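# Event-stream to daily 96-bin activity conversion and adequacy filters.

#' Aggregate interaction events into daily 15-min activity bins
#'
#' Converts a stream of timestamped human-smartphone interaction events
#' (taps, scrolls, typing, app changes, screen-on) into one row per
#' patient-day holding 96 binary bins: bin k covers the half-open interval
#' \code{[15k, 15(k+1))} minutes after local midnight and is active iff at
#' least one event starts inside it. Calendar days with no events that fall
#' between a patient's first and last observed event are emitted as all-zero
#' rows (they are inadequate by the 4-unique-hour rule and filtered
#' downstream rather than silently dropped). Day boundaries follow the clock
#' labels of a single configured timezone; on DST transitions duplicated or
#' skipped clock labels are OR-ed into the same bin.
#'
#' @param events data.frame with columns \code{patient_id},
#'   \code{timestamp} (POSIXct, or character parseable as
#'   \code{"YYYY-mm-dd HH:MM:SS"}), and optionally \code{event_type}
#'   (ignored: all interaction types count equally).
#' @param tz timezone used to slice days ("UTC" by default).
#' @return data.frame with columns \code{patient_id}, \code{date},
#'   \code{bins} (a 96-column 0/1 matrix column), \code{unique_active_hours}
#'   (number of distinct clock hours containing an active bin) and
#'   \code{adequate} (\code{unique_active_hours >= 4}).
#' @export
bin_events <- function(events, tz = "UTC") {
  pid <- as.character(events$patient_id)
  ts <- events$timestamp
  if (!inherits(ts, "POSIXct")) {
    ch <- as.character(ts)
    ts <- as.POSIXct(strptime(ch, "%Y-%m-%d %H:%M:%OS", tz = tz))
    retry <- is.na(ts)
    if (any(retry)) {
      ts[retry] <- as.POSIXct(strptime(ch[retry], "%Y-%m-%dT%H:%M:%OS",
                                       tz = tz))
    }
  }
  bad <- is.na(ts)
  if (any(bad)) {
    warning(sprintf("skipped %d event(s) with unparseable timestamps",
                    sum(bad)))
    pid <- pid[!bad]
    ts <- ts[!bad]
  }
  if (!length(ts)) {
    out <- data.frame(patient_id = character(), date = as.Date(character()),
                      stringsAsFactors = FALSE)
    out$bins <- matrix(0L, 0L, 96L)
    out$unique_active_hours <- integer()
    out$adequate <- logical()
    return(out)
  }
  if (identical(tz, "UTC")) {
    secs <- as.numeric(ts)
    daynum <- floor(secs / 86400)
    bin <- as.integer((secs - daynum * 86400) %/% 900)
  } else {
    lt <- as.POSIXlt(ts, tz = tz)
    daynum <- as.integer(as.Date(lt))
    bin <- as.integer((lt$hour * 3600L + lt$min * 60L + floor(lt$sec)) %/% 900)
  }
  bin[bin > 95L] <- 95L              # guard leap-second style edge values

  up <- sort(unique(pid))        # canonical order: input order is irrelevant
  pidx <- match(pid, up)
  dmin <- as.integer(tapply(daynum, pidx, min))
  dmax <- as.integer(tapply(daynum, pidx, max))
  ndays <- dmax - dmin + 1L
  offset <- cumsum(c(0L, ndays[-length(ndays)]))
  row <- offset[pidx] + as.integer(daynum - dmin[pidx]) + 1L

  mat <- matrix(0L, sum(ndays), 96L)
  mat[cbind(row, bin + 1L)] <- 1L
  hour_active <- matrix(0L, nrow(mat), 24L)
  for (h in 0:23) {
    hour_active[, h + 1L] <-
      as.integer(rowSums(mat[, (4L * h + 1L):(4L * h + 4L), drop = FALSE]) > 0L)
  }
  uah <- as.integer(rowSums(hour_active))

  out <- data.frame(
    patient_id = rep(up, ndays),
    date = as.Date(unlist(mapply(seq.int, dmin, dmax, SIMPLIFY = FALSE)),
                   origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  out$bins <- mat
  out$unique_active_hours <- uah
  out$adequate <- uah >= 4L
  out
}

#' Patients with adequate data coverage
#'
#' A patient is retained when at least \code{min_days} of their observed
#' days are adequate (activity in >= 4 distinct clock hours). The adequate
#' days need not be consecutive.
#'
#' @param activity day-level activity from [bin_events()].
#' @param min_days minimum number of adequate days (28, i.e. four weeks).
#' @return character vector of retained patient ids.
#' @export
adequate_patients <- function(activity, min_days = 28L) {
  if (!nrow(activity)) return(character())
  n_adq <- rowsum(as.integer(activity$adequate),
                  as.character(activity$patient_id))
  rownames(n_adq)[n_adq[, 1L] >= min_days]
}

#' Assign days to consecutive non-overlapping windows
#'
#' Windows are anchored at each patient's first observed day (not a global
#' calendar), so window index w covers days \code{[w*window_len,
#' (w+1)*window_len)} after that anchor and every calendar day maps to
#' exactly one window.
#'
#' @param activity day-level activity from [bin_events()] (any data.frame
#'   with \code{patient_id} and \code{date} works).
#' @param window_len window length in days.
#' @return data.frame \code{patient_id}, \code{date}, \code{window_index}.
#' @export
assign_windows <- function(activity, window_len = 30L) {
  pid <- as.character(activity$patient_id)
  day <- as.integer(activity$date)
  first <- stats::ave(day, pid, FUN = min)
  data.frame(patient_id = pid, date = activity$date,
             window_index = (day - first) %/% as.integer(window_len),
             stringsAsFactors = FALSE)
}
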