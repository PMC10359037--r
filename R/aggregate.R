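# Survey scoring, 14-day pre-survey aggregation and the within/between
# person decomposition of the behavioral predictors.

.domain_item_sets <- list(sleep = "sleep",
                          depression = c("anhedonia", "depressed_mood"),
                          anxiety = c("nervous", "panic", "avoidance"))

#' Score DSM-5 L1 symptom domains from item responses
#'
#' Computes the three domain scores used as model outcomes: sleep
#' disturbance (single item), depressive symptoms (mean of anhedonia and
#' depressed mood) and anxiety symptoms (mean of nervous, panic and
#' avoidance), each on the 0-4 Likert scale. A domain with any missing item
#' is absent for that survey; other domains on the same survey are
#' unaffected. Responses outside 0..4 invalidate the whole survey row, with
#' a warning carrying the count.
#'
#' @param items long data.frame \code{patient_id}, \code{date},
#'   \code{item_id}, \code{response}.
#' @return one row per survey: \code{patient_id}, \code{date}, and numeric
#'   columns \code{sleep}, \code{depression}, \code{anxiety} (NA when the
#'   domain is incomplete).
#' @export
score_surveys <- function(items) {
  resp <- items$response
  bad <- !is.na(resp) & (resp < 0 | resp > 4 | resp != round(resp))
  if (any(bad)) {
    drop_key <- unique(paste(items$patient_id, items$date)[bad])
    warning(sprintf("rejected %d survey(s) with out-of-range responses",
                    length(drop_key)))
    items <- items[!(paste(items$patient_id, items$date) %in% drop_key), ]
  }
  key <- paste(items$patient_id, items$date, sep = "\r")
  uk <- unique(key)
  gi <- match(key, uk)
  first <- match(seq_along(uk), gi)
  out <- data.frame(patient_id = items$patient_id[first],
                    date = items$date[first], stringsAsFactors = FALSE)
  for (dom in names(.domain_item_sets)) {
    set <- .domain_item_sets[[dom]]
    score <- rep(NA_real_, length(uk))
    sub <- items$item_id %in% set & !is.na(items$response)
    cnt <- tabulate(gi[sub], length(uk))
    sm <- rep(0, length(uk))
    if (any(sub)) {
      s <- rowsum(as.numeric(items$response[sub]), gi[sub])
      sm[as.integer(rownames(s))] <- s[, 1L]
    }
    full <- cnt == length(set)
    score[full] <- sm[full] / length(set)
    out[[dom]] <- score
  }
  out[order(out$patient_id, out$date), , drop = FALSE]
}

#' Attach pre-survey behavioral aggregates to survey occasions
#'
#' For every survey occasion, averages the daily overlap fraction,
#' disruption count and ESP duration over the viable days in the
#' \code{agg_days} calendar days ending the day before the survey (the
#' survey day itself is excluded: the instrument asks about the past two
#' weeks, and same-day behavior postdates part of the recall window).
#' Occasions with fewer than \code{min_viable_days} viable days are flagged
#' \code{retained = FALSE} and carry NA aggregates; they are excluded from
#' modeling but kept in the output so nothing is silently dropped.
#'
#' @param measures daily measures from [daily_measures()].
#' @param occasions data.frame with \code{patient_id} and \code{date} (one
#'   row per survey occasion); a [score_surveys()] result works directly,
#'   and any extra columns are carried through.
#' @param agg_days length of the look-back window in days.
#' @param min_viable_days minimum viable days for retention.
#' @return \code{occasions} with added columns \code{n_viable},
#'   \code{agg_overlap}, \code{agg_disruption}, \code{agg_duration},
#'   \code{retained}.
#' @export
aggregate_presurvey <- function(measures, occasions, agg_days = 14L,
                                min_viable_days = 3L) {
  out <- occasions
  n <- nrow(out)
  out$n_viable <- 0L
  out$agg_overlap <- NA_real_
  out$agg_disruption <- NA_real_
  out$agg_duration <- NA_real_
  vi <- measures[measures$viable, , drop = FALSE]
  vday <- as.integer(vi$date)
  vpid <- as.character(vi$patient_id)
  sday <- as.integer(out$date)
  spid <- as.character(out$patient_id)
  by_pid <- split(seq_len(nrow(vi)), vpid)
  for (i in seq_len(n)) {
    j <- by_pid[[spid[i]]]
    if (is.null(j)) next
    sel <- j[vday[j] >= sday[i] - agg_days & vday[j] < sday[i]]
    out$n_viable[i] <- length(sel)
    if (length(sel)) {
      out$agg_overlap[i] <- mean(vi$overlap[sel])
      out$agg_disruption[i] <- mean(vi$disruptions[sel])
      out$agg_duration[i] <- mean(vi$esp_duration_h[sel])
    }
  }
  out$retained <- out$n_viable >= min_viable_days
  out$agg_overlap[!out$retained] <- NA_real_
  out$agg_disruption[!out$retained] <- NA_real_
  out$agg_duration[!out$retained] <- NA_real_
  out
}

#' Split behavioral aggregates into within- and between-person components
#'
#' For each behavioral aggregate x, the between-person component bp_x is the
#' person's mean over their retained occasions and the within-person
#' component is the occasion deviation wp_x = x - bp_x, so wp_x + bp_x
#' reconstructs the aggregate exactly and wp_x averages to zero within each
#' person. Non-retained occasions get NA components (their aggregates are
#' undefined) and do not influence the person means.
#'
#' @param rows output of [aggregate_presurvey()].
#' @return \code{rows} with added \code{wp_overlap}, \code{wp_disruption},
#'   \code{wp_duration}, \code{bp_overlap}, \code{bp_disruption},
#'   \code{bp_duration}.
#' @export
split_within_between <- function(rows) {
  for (v in c("overlap", "disruption", "duration")) {
    x <- rows[[paste0("agg_", v)]]
    bp <- rep(NA_real_, nrow(rows))
    r <- rows$retained
    if (any(r)) {
      bp[r] <- stats::ave(x[r], rows$patient_id[r])
    }
    rows[[paste0("bp_", v)]] <- bp
    rows[[paste0("wp_", v)]] <- x - bp
  }
  rows
}

#' Build model-ready observation rows from pipeline outputs
#'
#' Convenience wrapper chaining [score_surveys()], [aggregate_presurvey()],
#' [split_within_between()] and a demographics merge into the observation
#' table the models consume. Only occasions passing the minimum-viable-days
#' rule are returned.
#'
#' @param measures daily measures from [daily_measures()].
#' @param surveys long item responses (see [score_surveys()]).
#' @param demographics per-patient demographics table.
#' @param agg_days,min_viable_days see [aggregate_presurvey()].
#' @return data.frame with one row per retained survey occasion: outcome
#'   scores (\code{sleep}, \code{depression}, \code{anxiety}), wp_/bp_
#'   predictor components, and demographics.
#' @export
build_observation_rows <- function(measures, surveys, demographics,
                                   agg_days = 14L, min_viable_days = 3L) {
  scored <- score_surveys(surveys)
  occ <- aggregate_presurvey(measures, scored, agg_days, min_viable_days)
  occ <- split_within_between(occ)
  occ <- occ[occ$retained, , drop = FALSE]
  merge(occ, demographics, by = "patient_id", sort = FALSE)
}

#' Weekday versus weekend behavioral summary by age decade
#'
#' A descriptive post hoc table: per age decade, the mean daily overlap
#' fraction and disruption count on weekdays versus weekends
#' (Saturday/Sunday), with their differences. Only viable days contribute;
#' empty groups are omitted.
#'
#' @param measures daily measures from [daily_measures()].
#' @param demographics per-patient table with an \code{age} column.
#' @return data.frame with one row per age decade.
#' @export
weekday_weekend_summary <- function(measures, demographics) {
  vi <- measures[measures$viable, , drop = FALSE]
  if (!nrow(vi)) return(data.frame())
  age <- demographics$age[match(as.character(vi$patient_id),
                                demographics$patient_id)]
  decade <- (as.integer(age) %/% 10L) * 10L
  dow <- (as.integer(vi$date) + 4L) %% 7L     # 0 = Sunday
  weekend <- dow %in% c(0L, 6L)
  out <- list()
  for (d in sort(unique(decade[!is.na(decade)]))) {
    g <- which(decade == d)
    we <- g[weekend[g]]
    wd <- g[!weekend[g]]
    if (!length(we) || !length(wd)) next
    out[[length(out) + 1L]] <- data.frame(
      age_decade = d,
      n_weekday = length(wd), n_weekend = length(we),
      overlap_weekday = mean(vi$overlap[wd]),
      overlap_weekend = mean(vi$overlap[we]),
      overlap_diff = mean(vi$overlap[we]) - mean(vi$overlap[wd]),
      disruptions_weekday = mean(vi$disruptions[wd]),
      disruptions_weekend = mean(vi$disruptions[we]),
      disruptions_diff = mean(vi$disruptions[we]) - mean(vi$disruptions[wd]))
  }
  do.call(rbind, out)
}
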