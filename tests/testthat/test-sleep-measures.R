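# Daily ISP, windowed ESP, k-means binarization, overlap and disruptions.

test_that("isp_span handles whole-day, no-inactivity and competing runs", {
  expect_equal(isp_span(integer(96)),
               list(start = 0L, length = 96L, circular = FALSE))
  expect_null(isp_span(rep(1L, 96)))

  # inactive runs of 13 and 7 bins separated by activity: longest wins
  b <- rep(1L, 96)
  b[10:22] <- 0L   # 13 bins
  b[40:46] <- 0L   # 7 bins
  sp <- isp_span(b)
  expect_equal(sp$start, 9L)
  expect_equal(sp$length, 13L)

  # equal-length runs: earliest start wins
  b <- rep(1L, 96)
  b[5:10] <- 0L
  b[50:55] <- 0L
  expect_equal(isp_span(b)$start, 4L)
})

test_that("isp_span matches the exhaustive scan on random days", {
  set.seed(101)
  for (i in 1:500) {
    b <- rbinom(96, 1, runif(1, 0.1, 0.9))
    got <- isp_span(b)
    want <- oracle_longest_zero_run(b)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$length, want$length)
    }
  }
})

test_that("esp_span treats the profile circularly", {
  b <- rep(1L, 96)
  b[1:32] <- 0L          # bins 0-31
  sp <- esp_span(b)
  expect_equal(sp$start, 0L)
  expect_equal(sp$length, 32L)
  expect_false(sp$circular)
  expect_equal(sp$length * 0.25, 8)   # 8 h nocturnal window

  # wrap past midnight: 92-95 and 0-27 form one 32-bin run
  b <- rep(1L, 96)
  b[93:96] <- 0L
  b[1:28] <- 0L
  sp <- esp_span(b)
  expect_equal(sp$start, 92L)
  expect_equal(sp$length, 32L)
  expect_true(sp$circular)

  # all-zero profile: degenerate full-day span
  sp <- esp_span(integer(96))
  expect_equal(sp$length, 96L)
  expect_true(sp$degenerate)

  # no inactive bin
  expect_null(esp_span(rep(1L, 96)))
})

test_that("esp_span length agrees with the circular brute force", {
  set.seed(202)
  for (i in 1:300) {
    b <- rbinom(96, 1, runif(1, 0.2, 0.8))
    got <- esp_span(b)
    if (all(b == 1L)) {
      expect_null(got)
    } else {
      expect_equal(got$length, oracle_longest_zero_run_circular(b))
      # returned span is genuinely all-zero and maximal
      bins <- span_bins(got)
      expect_true(all(b[bins + 1L] == 0L))
      if (got$length < 96L) {
        before <- (got$start - 1L) %% 96L
        after <- (got$start + got$length) %% 96L
        expect_true(b[before + 1L] == 1L && b[after + 1L] == 1L)
      }
    }
  }
})

test_that("binarize_fraction separates well-separated clusters and rejects
           constant profiles", {
  f <- c(rep(0.9, 64), rep(0.05, 32))
  z <- binarize_fraction(f)
  expect_equal(z, c(rep(1L, 64), rep(0L, 32)))
  expect_null(binarize_fraction(rep(0.5, 96)))
  expect_error(binarize_fraction(rep(1.5, 96)), "0, 1")
})

test_that("binarize_fraction attains the exhaustive threshold optimum", {
  set.seed(303)
  wcss <- function(x, a) {
    sum((x[a == 0] - mean(x[a == 0]))^2) +
      sum((x[a == 1] - mean(x[a == 1]))^2)
  }
  for (i in 1:200) {
    x <- switch(1 + i %% 3,
                runif(96),
                pmin(pmax(c(rnorm(60, 0.7, 0.15), rnorm(36, 0.1, 0.05)),
                          0), 1),
                rbeta(96, 0.5, 0.5))
    got <- binarize_fraction(x)
    want <- oracle_two_means(x)
    expect_equal(got, want)
    expect_equal(wcss(x, got), wcss(x, want))
  }
})

test_that("overlap_pct implements the duration-naive worked examples", {
  esp <- list(start = 0L, length = 32L)       # 00:00-08:00
  # 25-bin ISP entirely inside the ESP: 100%
  isp <- list(start = 3L, length = 25L)
  expect_equal(overlap_pct(isp, esp), 1.0)
  # 13-bin ISP with 12 bins inside: 12/13 ~ 92%
  isp <- list(start = 20L, length = 13L)
  expect_equal(overlap_pct(isp, esp), 12 / 13)
  expect_equal(round(100 * overlap_pct(isp, esp)), 92)
  # disjoint spans
  expect_equal(overlap_pct(list(start = 50L, length = 10L), esp), 0)
  # absent span propagates
  expect_true(is.na(overlap_pct(NULL, esp)))
  expect_true(is.na(overlap_pct(isp, NULL)))
})

test_that("overlap is monotone when the ESP shrinks and total when inside", {
  set.seed(404)
  for (i in 1:100) {
    isp <- list(start = sample(0:80, 1), length = sample(1:15, 1))
    len <- sample(10:60, 1)
    esp_big <- list(start = sample(0:95, 1), length = len)
    esp_small <- list(start = esp_big$start, length = sample(1:len, 1))
    expect_lte(overlap_pct(isp, esp_small), overlap_pct(isp, esp_big))
    inside <- all(span_bins(isp) %in% span_bins(esp_big))
    expect_equal(overlap_pct(isp, esp_big) == 1, inside)
  }
})

test_that("disruption_count counts active bins inside the ESP", {
  esp <- list(start = 0L, length = 31L)       # 00:00-07:45
  day <- day_bins(c(2, 10, 17, 25, 30, 40, 50, 60))  # 5 inside, 3 outside
  expect_equal(disruption_count(day, esp), 5L)
  expect_equal(disruption_count(integer(96), esp), 0L)
  # every ESP bin active: count equals the ESP length
  expect_equal(disruption_count(rep(1L, 96), esp), esp$length)
  # count never exceeds the ESP length
  set.seed(505)
  for (i in 1:50) {
    d <- rbinom(96, 1, 0.5)
    expect_lte(disruption_count(d, esp), esp$length)
  }
})

test_that("window_profiles marks short and sparse windows invalid", {
  # 72 days: two complete 30-day windows plus a 12-day trailing remnant
  dates <- as.Date("2021-03-01") + 0:71
  days <- lapply(1:72, function(i) {
    if (i <= 30 && i %% 2 == 0) inadequate_day() else adequate_day()
  })
  act <- make_activity("A", dates, days)
  prof <- window_profiles(act)
  expect_equal(nrow(prof), 3L)
  # window 0 has 15 adequate days: valid; window 1 fully adequate: valid
  expect_true(prof$valid[prof$window_index == 1])
  expect_equal(prof$n_adequate[prof$window_index == 0], 15L)
  expect_true(prof$valid[prof$window_index == 0])
  # trailing 12-day window invalid regardless of adequacy
  expect_false(prof$valid[prof$window_index == 2])

  # 14 adequate days in a 30-day window: invalid
  days <- lapply(1:30, function(i) {
    if (i <= 14) adequate_day() else inadequate_day()
  })
  act <- make_activity("B", as.Date("2021-03-01") + 0:29, days)
  prof <- window_profiles(act)
  expect_false(any(prof$valid))
})

test_that("daily measures are present exactly on viable days", {
  co <- simulate_cohort(sim_config(n_patients = 4, days_per_patient = 70,
                                   seed = 77, extra_domains = list()))
  m <- co$measures
  expect_true(all(!is.na(m$overlap[m$viable])))
  expect_true(all(!is.na(m$disruptions[m$viable])))
  expect_true(all(is.na(m$overlap[!m$viable])))
  expect_true(all(m$overlap[m$viable] >= 0 & m$overlap[m$viable] <= 1))
  expect_true(all(m$disruptions[m$viable] >= 0))
})
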