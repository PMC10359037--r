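# Survey scoring, pre-survey aggregation and within/between decomposition.

mk_measures <- function(pid, dates, overlap, disruptions = 2,
                        duration = 8, viable = TRUE) {
  data.frame(patient_id = pid, date = dates,
             overlap = overlap,
             disruptions = rep_len(disruptions, length(dates)),
             esp_duration_h = rep_len(duration, length(dates)),
             viable = rep_len(viable, length(dates)),
             stringsAsFactors = FALSE)
}

mk_items <- function(pid, date, responses) {
  data.frame(patient_id = pid, date = as.Date(date),
             item_id = names(responses),
             response = unname(unlist(responses)),
             stringsAsFactors = FALSE)
}

test_that("domain scores are item means, absent when any item is missing", {
  it <- rbind(
    mk_items("A", "2021-06-01",
             c(sleep = 4, anhedonia = 1, depressed_mood = 2,
               nervous = 2, panic = 3, avoidance = 4)),
    mk_items("A", "2021-07-01",
             c(sleep = 1, anhedonia = 1, depressed_mood = NA,
               nervous = 0, panic = 0, avoidance = 0)))
  s <- score_surveys(it)
  expect_equal(s$sleep, c(4, 1))
  expect_equal(s$depression, c(1.5, NA))
  expect_equal(s$anxiety, c(3, 0))
})

test_that("out-of-range responses reject the survey with a warning", {
  it <- rbind(mk_items("A", "2021-06-01", c(sleep = 7)),
              mk_items("A", "2021-07-01", c(sleep = 2)))
  expect_warning(s <- score_surveys(it), "out-of-range")
  expect_equal(nrow(s), 1L)
  expect_equal(s$sleep, 2)
})

test_that("pre-survey aggregates average viable days, excluding the survey
           day, and enforce the 3-day rule", {
  d0 <- as.Date("2021-06-15")
  meas <- rbind(
    mk_measures("A", d0 - c(1, 5, 9), overlap = c(1.0, 0.9, 0.5)),
    mk_measures("A", d0, overlap = 0.0),               # survey day itself
    mk_measures("A", d0 - 15, overlap = 0.0),          # outside 14 days
    mk_measures("B", d0 - c(2, 4), overlap = c(0.2, 0.4)))
  occ <- data.frame(patient_id = c("A", "B"), date = d0,
                    stringsAsFactors = FALSE)
  agg <- aggregate_presurvey(meas, occ)
  expect_equal(agg$n_viable, c(3L, 2L))
  expect_equal(agg$agg_overlap[1], 0.8)     # mean of 1.0, 0.9, 0.5
  expect_true(agg$retained[1])
  expect_false(agg$retained[2])             # only 2 viable days
  expect_true(is.na(agg$agg_overlap[2]))
})

test_that("constant 14 viable days reproduce their value exactly", {
  d0 <- as.Date("2021-06-15")
  meas <- mk_measures("A", d0 - (1:14), overlap = 0.8)
  agg <- aggregate_presurvey(meas, data.frame(patient_id = "A", date = d0))
  expect_equal(agg$n_viable, 14L)
  expect_equal(agg$agg_overlap, 0.8)
})

test_that("occasions do not leak into each other's aggregates", {
  d0 <- as.Date("2021-06-15")
  meas <- mk_measures("A", d0 + c(-10:-1, 20:29),
                      overlap = runif(20))
  occ2 <- data.frame(patient_id = "A", date = c(d0, d0 + 30))
  occ1 <- occ2[1, , drop = FALSE]
  a2 <- aggregate_presurvey(meas, occ2)
  a1 <- aggregate_presurvey(meas, occ1)
  expect_equal(a1$agg_overlap, a2$agg_overlap[1])
  expect_equal(a1$n_viable, a2$n_viable[1])
})

test_that("within/between split reconstructs aggregates and centers wp", {
  occ <- data.frame(patient_id = c("A", "A", "B"),
                    date = as.Date("2021-06-01") + c(0, 30, 0),
                    n_viable = 5L,
                    agg_overlap = c(0.6, 0.8, 0.5),
                    agg_disruption = c(2, 4, 1),
                    agg_duration = c(8, 7, 9),
                    retained = TRUE, stringsAsFactors = FALSE)
  sp <- split_within_between(occ)
  expect_equal(sp$bp_overlap, c(0.7, 0.7, 0.5))
  expect_equal(sp$wp_overlap, c(-0.1, 0.1, 0))   # single occasion: wp = 0
  expect_equal(sp$wp_overlap + sp$bp_overlap, occ$agg_overlap)
  expect_equal(sp$wp_disruption + sp$bp_disruption, occ$agg_disruption,
               tolerance = 1e-12)
})

test_that("per-person within components sum to zero on simulated cohorts", {
  co <- simulate_cohort(sim_config(n_patients = 10, days_per_patient = 120,
                                   seed = 41, extra_domains = list()))
  occ <- co$occasions[co$occasions$retained, ]
  for (v in c("wp_overlap", "wp_disruption", "wp_duration")) {
    expect_true(all(abs(tapply(occ[[v]], occ$patient_id, sum)) < 1e-9))
  }
  # units sanity on every observation row
  rows <- build_observation_rows(co$measures, co$surveys, co$demographics)
  expect_true(all(rows$agg_overlap >= 0 & rows$agg_overlap <= 1))
  expect_true(all(rows$agg_disruption >= 0))
  expect_true(all(rows$agg_duration > 0 & rows$agg_duration <= 24))
})

test_that("weekday/weekend contrast is null without a generated shift and
           negative in overlap with a weekend onset delay", {
  base <- list(n_patients = 25, days_per_patient = 120,
               onset_jitter_sd_h = 0.5, onset_jitter_spread_h = 0.2,
               extra_domains = list(), seed = 61)
  pooled <- function(tab, col_we, col_wd) {
    (sum(tab$n_weekend * tab[[col_we]]) / sum(tab$n_weekend)) -
      (sum(tab$n_weekday * tab[[col_wd]]) / sum(tab$n_weekday))
  }
  co0 <- simulate_cohort(do.call(sim_config,
                                 c(base, weekend_onset_shift_h = 0)))
  t0 <- weekday_weekend_summary(co0$measures, co0$demographics)
  expect_lt(abs(pooled(t0, "overlap_weekend", "overlap_weekday")), 0.05)

  co1 <- simulate_cohort(do.call(sim_config,
                                 c(base, weekend_onset_shift_h = 1.5)))
  t1 <- weekday_weekend_summary(co1$measures, co1$demographics)
  expect_lt(pooled(t1, "overlap_weekend", "overlap_weekday"), -0.02)
})
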