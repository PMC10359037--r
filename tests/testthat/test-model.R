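# Demographic screening, influence filtering, the two-level fit and the
# KS stability check.

test_that("cooks_filter removes a gross outlier and nothing degenerate", {
  rows <- simulate_observation_rows(n_patients = 40, n_occasions = 5,
                                    seed = 11)
  shifted <- rows
  shifted$sleep[17] <- shifted$sleep[17] + 50
  cf <- cooks_filter(shifted, "sleep")
  expect_true(17 %in% as.integer(rownames(cf$removed)) ||
                nrow(cf$removed) >= 1)
  expect_false(any(abs(cf$retained$sleep - mean(rows$sleep)) > 40))

  # all rows identical: perfect fit, all distances zero, nothing removed
  same <- rows[rep(1, 20), ]
  cf0 <- cooks_filter(same, "sleep")
  expect_equal(cf0$removed_fraction, 0)
  expect_equal(nrow(cf0$retained), 20L)
})

test_that("cooks_filter names collinear columns on a singular design", {
  rows <- simulate_observation_rows(n_patients = 30, n_occasions = 4,
                                    seed = 12)
  rows$bp_duration <- 2 * rows$bp_overlap + 1    # exact collinearity
  expect_error(cooks_filter(rows, "sleep"), "bp_duration")
})

test_that("screening includes strong effects and excludes high-missingness
           or constant variables", {
  rows <- simulate_observation_rows(n_patients = 80, n_occasions = 4,
                                    seed = 13)
  rows$depression <- rows$sleep          # second outcome, same structure
  rows$strong <- rnorm(nrow(rows))
  rows$strong <- stats::ave(rows$strong, rows$patient_id)  # person-level
  rows$sleep <- rows$sleep + 2 * rows$strong
  rows$mostly_missing <- ifelse(runif(nrow(rows)) < 0.5, 1, NA)
  rows$constant <- 1
  scr <- suppressWarnings(
    screen_demographics(rows, c("age", "strong", "mostly_missing",
                                "constant"),
                        outcomes = c("sleep", "depression")))
  expect_true("strong" %in% scr$included)
  expect_match(scr$excluded[["mostly_missing"]], "missingness")
  expect_equal(scr$excluded[["constant"]], "constant")
})

test_that("screening regressions hold their size under the null", {
  # a pure-noise person-level demographic tested against one outcome:
  # the per-regression rejection rate stays near alpha
  p <- replicate(60, {
    rows <- simulate_observation_rows(n_patients = 40, n_occasions = 4,
                                      seed = sample.int(1e6, 1))
    rows$noise <- rep(rnorm(40), each = 4)
    scr <- screen_demographics(rows, "noise", outcomes = "sleep")
    scr$table$p_value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.0)
  expect_lt(rate, 0.15)
})

test_that("the two-level fit recovers generating parameters on direct
           simulations", {
  rows <- simulate_observation_rows(n_patients = 250, n_occasions = 8,
                                    seed = 14)
  m <- fit_symptom_model(rows, "sleep", influence = "none")
  tab <- m$coefficients
  g <- sleeptrace:::.domain_presets$sleep$fixed_effects
  for (term in c("wp_disruption", "bp_disruption", "bp_overlap")) {
    row <- tab[tab$term == term, ]
    expect_lt(abs(row$estimate - g[[term]]), 3 * row$std_error)
  }
  expect_lt(abs(m$varcomp[["residual"]] - 0.67), 0.15)
  expect_lt(abs(m$varcomp[["intercept"]] - 0.97), 0.4)
})

test_that("estimates are invariant to row order and patient relabeling", {
  rows <- simulate_observation_rows(n_patients = 60, n_occasions = 4,
                                    seed = 15)
  m1 <- fit_symptom_model(rows, "sleep", influence = "none")
  set.seed(1)
  perm <- rows[sample(nrow(rows)), ]
  perm$patient_id <- paste0("XX_", perm$patient_id)
  m2 <- fit_symptom_model(perm, "sleep", influence = "none")
  expect_equal(coef(m1), coef(m2), tolerance = 1e-6)
})

test_that("dropping null random slopes barely moves the fixed effects", {
  rows <- simulate_observation_rows(
    n_patients = 100, n_occasions = 5,
    re_variances = c(intercept = 0.9, wp_overlap = 0, wp_disruption = 0,
                     wp_duration = 0),
    seed = 16)
  m_full <- fit_symptom_model(rows, "sleep", influence = "none")
  m_int <- fit_symptom_model(rows, "sleep", influence = "none",
                             random_slopes = FALSE)
  se <- m_int$coefficients$std_error
  expect_true(all(abs(coef(m_full) - coef(m_int)) <= se))
})

test_that("symptom_lmm methods behave like a classed model fit", {
  rows <- simulate_observation_rows(n_patients = 50, n_occasions = 4,
                                    seed = 17)
  m <- fit_symptom_model(rows, "sleep", influence = "cooks")
  expect_s3_class(m, "symptom_lmm")
  expect_output(print(m), "Fixed effects")
  expect_named(coef(m))
  ci <- confint(m)
  expect_true(all(ci[, 1] <= coef(m) & coef(m) <= ci[, 2]))
  expect_equal(nobs(m), m$n_obs)
  expect_equal(length(residuals(m)), m$n_obs)
  expect_equal(length(predict(m)), m$n_obs)
  s <- summary(m)
  expect_s3_class(s, "summary.symptom_lmm")
  expect_true(all(c("estimate", "p_value", "ci_lower") %in%
                    names(s$coefficients)))
  sim <- simulate(m, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(m$n_obs, 2L))
})

test_that("ks_compare flags only real distributional change", {
  rows <- simulate_observation_rows(n_patients = 40, n_occasions = 4,
                                    seed = 18)
  same <- ks_compare(rows, rows, c("sleep", "bp_overlap"))
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_value == 1))
  shifted <- rows
  shifted$sleep <- shifted$sleep + 100   # disjoint supports
  ks <- ks_compare(rows, shifted, "sleep")
  expect_equal(ks$statistic, 1)
  expect_lt(ks$p_value, 1e-10)
  expect_error(ks_compare(rows[0, ], rows), "non-empty")
})
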