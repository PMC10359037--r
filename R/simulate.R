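# Synthetic cohort generator: circadian event streams with known ground
# truth, plus symptom surveys generated from the two-level model so that
# every downstream stage of the pipeline is testable without real data.

.coef_names <- c("intercept", "wp_overlap", "wp_disruption", "wp_duration",
                 "bp_overlap", "bp_disruption", "bp_duration",
                 "age", "gender_male", "pd_majordep", "pd_personality",
                 "pd_schizophrenia", "location_rural")

.re_names <- c("intercept", "wp_overlap", "wp_disruption", "wp_duration")

# Published multilevel estimates used as generating values, one column per
# symptom domain (order follows .coef_names / .re_names).
.domain_presets <- list(
  sleep = list(
    fixed_effects = c(intercept = 2.49, wp_overlap = -0.21,
                      wp_disruption = 0.045, wp_duration = -0.03,
                      bp_overlap = -0.90, bp_disruption = 0.098,
                      bp_duration = 0.015, age = -0.0044,
                      gender_male = -0.0012, pd_majordep = -0.0052,
                      pd_personality = 0.11, pd_schizophrenia = -0.40,
                      location_rural = -0.065),
    re_variances = c(intercept = 0.97, wp_overlap = 0.28,
                     wp_disruption = 0.0012, wp_duration = 0.0082),
    resid_variance = 0.67),
  depression = list(
    fixed_effects = c(intercept = 2.37, wp_overlap = 0.015,
                      wp_disruption = 0.0004, wp_duration = 0.0055,
                      bp_overlap = -0.80, bp_disruption = 0.053,
                      bp_duration = 0.061, age = -0.0034,
                      gender_male = -0.020, pd_majordep = 0.086,
                      pd_personality = 0.28, pd_schizophrenia = -0.27,
                      location_rural = -0.065),
    re_variances = c(intercept = 0.65, wp_overlap = 0.020,
                     wp_disruption = 0.0005, wp_duration = 0.0033),
    resid_variance = 0.43),
  anxiety = list(
    fixed_effects = c(intercept = 2.51, wp_overlap = -0.07,
                      wp_disruption = 0.013, wp_duration = -0.0078,
                      bp_overlap = -0.66, bp_disruption = 0.048,
                      bp_duration = 0.069, age = -0.011,
                      gender_male = 0.077, pd_majordep = -0.078,
                      pd_personality = 0.21, pd_schizophrenia = -0.17,
                      location_rural = -0.076),
    re_variances = c(intercept = 0.75, wp_overlap = 0.0,
                     wp_disruption = 0.0008, wp_duration = 0.0023),
    resid_variance = 0.35)
)

#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of the generator with defaults calibrated so that
#' the pipeline's measured moments on generated data emulate the reference
#' cohort: mean expected-sleep-period duration near 8.4 h (SD ~2.3), mean
#' daily overlap percentage in the mid-70s, and mean disruptions near 4.85
#' bins (SD ~3). The latent parameters differ from the measured targets
#' because the measures are imperfect: latent sleep of 8.8 h starting
#' around 23:30 yields a measured ESP of ~8.3 h once onset jitter blurs the
#' window edges, and a latent nightly disruption rate of 3 bins yields ~4.9
#' measured disruptions once jittered daytime activity spills into the ESP.
#' Surveys arrive every 30 days and symptom outcomes are generated from the
#' published two-level model estimates for the three DSM-5 L1 domains.
#'
#' @param n_patients number of patients.
#' @param days_per_patient observation days per patient; a scalar, or a
#'   length-2 range sampled uniformly per patient.
#' @param survey_interval_days days between consecutive surveys (>= 1).
#' @param sleep_onset_mean_h,sleep_onset_sd_h population mean and SD of the
#'   person-level habitual sleep-onset clock hour (24 = midnight).
#' @param sleep_duration_mean_h,sleep_duration_sd_h population mean and SD
#'   of person-level sleep duration, hours.
#' @param onset_jitter_sd_h mean of the person-specific day-to-day onset
#'   jitter SD, hours.
#' @param onset_jitter_spread_h population SD of that jitter SD (truncated
#'   at 0), hours.
#' @param disruption_rate expected number of active 15-min bins per night
#'   inside the sleep interval (population mean of the person rate).
#' @param disruption_rate_sd population SD of the person rate (truncated
#'   at 0).
#' @param daytime_activity_prob probability that a 15-min bin outside the
#'   sleep interval is active.
#' @param missing_day_prob probability that a calendar day has no events.
#' @param weekend_onset_shift_h extra sleep-onset delay on Friday and
#'   Saturday nights, hours (0 disables any weekday/weekend structure).
#' @param fixed_effects named numeric vector of generating coefficients for
#'   the sleep-disturbance outcome (names as in \code{.coef_names}:
#'   intercept, wp_/bp_ overlap, disruption, duration, and the demographic
#'   terms). Overlap enters on the 0-1 fraction scale, disruption as a bin
#'   count, duration in hours, age in uncentered years; gender, location
#'   and primary-diagnosis terms are 0/1 indicators with female/urban as
#'   reference.
#' @param re_variances named numeric vector of random-effect variances for
#'   the sleep-disturbance outcome (intercept and the three wp slopes; the
#'   effects are drawn independently with mean zero).
#' @param resid_variance residual variance of the sleep-disturbance outcome.
#' @param extra_domains named list of additional outcome domains, each a
#'   list with \code{fixed_effects}, \code{re_variances},
#'   \code{resid_variance}; defaults to the published depression and
#'   anxiety columns. Set to \code{list()} to generate sleep only.
#' @param start_date first observation date of every patient.
#' @param seed integer seed; a fixed seed makes regeneration byte-identical.
#' @return an object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_patients = 300L,
                       days_per_patient = 240L,
                       survey_interval_days = 30L,
                       sleep_onset_mean_h = 23.5,
                       sleep_onset_sd_h = 1.0,
                       sleep_duration_mean_h = 8.8,
                       sleep_duration_sd_h = 1.5,
                       onset_jitter_sd_h = 2.2,
                       onset_jitter_spread_h = 1.1,
                       disruption_rate = 3.0,
                       disruption_rate_sd = 1.5,
                       daytime_activity_prob = 0.45,
                       missing_day_prob = 0.10,
                       weekend_onset_shift_h = 0,
                       fixed_effects = .domain_presets$sleep$fixed_effects,
                       re_variances = .domain_presets$sleep$re_variances,
                       resid_variance = .domain_presets$sleep$resid_variance,
                       extra_domains = .domain_presets[c("depression",
                                                         "anxiety")],
                       start_date = as.Date("2021-01-01"),
                       seed = 1L) {
  fe <- .complete_coefs(fixed_effects, .coef_names)
  rv <- .complete_coefs(re_variances, .re_names)
  domains <- c(list(sleep = list(fixed_effects = fe, re_variances = rv,
                                 resid_variance = resid_variance)),
               lapply(extra_domains, function(d) {
                 list(fixed_effects = .complete_coefs(d$fixed_effects,
                                                      .coef_names),
                      re_variances = .complete_coefs(d$re_variances,
                                                     .re_names),
                      resid_variance = d$resid_variance)
               }))
  cfg <- list(n_patients = as.integer(n_patients),
              days_per_patient = as.integer(days_per_patient),
              survey_interval_days = as.integer(survey_interval_days),
              sleep_onset_mean_h = sleep_onset_mean_h,
              sleep_onset_sd_h = sleep_onset_sd_h,
              sleep_duration_mean_h = sleep_duration_mean_h,
              sleep_duration_sd_h = sleep_duration_sd_h,
              onset_jitter_sd_h = onset_jitter_sd_h,
              onset_jitter_spread_h = onset_jitter_spread_h,
              disruption_rate = disruption_rate,
              disruption_rate_sd = disruption_rate_sd,
              daytime_activity_prob = daytime_activity_prob,
              missing_day_prob = missing_day_prob,
              weekend_onset_shift_h = weekend_onset_shift_h,
              domains = domains,
              start_date = as.Date(start_date),
              seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# fill unnamed coefficients with 0 and order them canonically
.complete_coefs <- function(x, names_full) {
  out <- stats::setNames(numeric(length(names_full)), names_full)
  if (length(x)) {
    unknown <- setdiff(names(x), names_full)
    if (length(unknown)) {
      stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
    }
    out[names(x)] <- x
  }
  out
}

.validate_config <- function(cfg) {
  probs <- c(cfg$daytime_activity_prob, cfg$missing_day_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (cfg$survey_interval_days < 1L) stop("survey_interval_days must be >= 1")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (!length(cfg$days_per_patient) %in% c(1L, 2L) ||
      any(cfg$days_per_patient < 1L)) {
    stop("days_per_patient must be a positive scalar or length-2 range")
  }
  sds <- c(cfg$sleep_onset_sd_h, cfg$sleep_duration_sd_h,
           cfg$onset_jitter_sd_h, cfg$onset_jitter_spread_h,
           cfg$disruption_rate, cfg$disruption_rate_sd)
  if (any(sds < 0)) stop("rates and standard deviations must be >= 0")
  for (d in cfg$domains) {
    if (any(d$re_variances < 0) || d$resid_variance < 0) {
      stop("variances must be >= 0")
    }
  }
  invisible(TRUE)
}

# Table-1-style marginal frequencies for the demographic generator
.demo_marginals <- list(
  age_decade = c(`20` = 0.018, `30` = 0.071, `40` = 0.156, `50` = 0.284,
                 `60` = 0.350, `70` = 0.117),
  gender = c(female = 0.736, male = 0.251, unspecified = 0.010),
  ethnicity = c(White = 0.489, Black = 0.105, Hispanic = 0.034,
                Multiracial = 0.021, Other = 0.009, Unspecified = 0.343),
  diagnosis = c(majordep = 0.406, bipolar = 0.200, personality = 0.034,
                schizophrenia = 0.065, other = 0.291, missing = 0.003),
  location = c(urban = 0.447, rural = 0.553)
)

.simulate_demographics <- function(ids) {
  n <- length(ids)
  m <- .demo_marginals
  dec <- as.integer(sample(names(m$age_decade), n, replace = TRUE,
                           prob = m$age_decade))
  age <- dec + stats::runif(n) * 10
  gender <- sample(names(m$gender), n, replace = TRUE, prob = m$gender)
  eth <- sample(names(m$ethnicity), n, replace = TRUE, prob = m$ethnicity)
  eth[eth == "Unspecified"] <- NA_character_
  diag <- sample(names(m$diagnosis), n, replace = TRUE, prob = m$diagnosis)
  loc <- sample(names(m$location), n, replace = TRUE, prob = m$location)
  data.frame(patient_id = ids,
             age = round(age, 1),
             gender = gender,
             gender_male = as.integer(gender == "male"),
             ethnicity = eth,
             primary_diagnosis = diag,
             pd_majordep = as.integer(diag == "majordep"),
             pd_personality = as.integer(diag == "personality"),
             pd_schizophrenia = as.integer(diag == "schizophrenia"),
             location = loc,
             location_rural = as.integer(loc == "rural"),
             stringsAsFactors = FALSE)
}

#' Simulate smartphone interaction event streams
#'
#' Phase one of the two-phase generator. Each patient gets person-level
#' sleep parameters (habitual onset, duration, day-to-day onset jitter SD,
#' nightly disruption rate), demographics with realistic marginal
#' frequencies, and independent mean-zero random effects for every outcome
#' domain. Days are then built on a continuous timeline: every 15-min bin
#' outside the night's realized sleep interval is active with
#' \code{daytime_activity_prob}; bins inside it are inactive except for
#' disruption bins hit by a Poisson process with the person's nightly rate;
#' whole days go missing with \code{missing_day_prob}. Every active bin
#' emits one event at a uniform time within the bin. Sleep intervals may
#' cross midnight; slicing events into calendar days is left to
#' [bin_events()].
#'
#' @param config a [sim_config()] object.
#' @return list with \code{events} (patient_id, timestamp POSIXct UTC,
#'   event_type), \code{truth} (per-patient parameters and random effects),
#'   and \code{demographics}.
#' @export
simulate_events <- function(config = sim_config()) {
  .validate_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  onset <- stats::rnorm(n, config$sleep_onset_mean_h, config$sleep_onset_sd_h)
  dur <- pmin(pmax(stats::rnorm(n, config$sleep_duration_mean_h,
                                config$sleep_duration_sd_h), 3), 14)
  jit <- pmax(stats::rnorm(n, config$onset_jitter_sd_h,
                           config$onset_jitter_spread_h), 0)
  disr <- pmax(stats::rnorm(n, config$disruption_rate,
                            config$disruption_rate_sd), 0)
  D <- if (length(config$days_per_patient) == 2L) {
    sample(config$days_per_patient[1L]:config$days_per_patient[2L], n,
           replace = TRUE)
  } else rep.int(config$days_per_patient, n)

  demo <- .simulate_demographics(ids)
  truth <- data.frame(patient_id = ids, n_days = D, onset_h = onset,
                      duration_h = dur, jitter_sd_h = jit,
                      disruption_rate = disr, stringsAsFactors = FALSE)
  for (dom in names(config$domains)) {
    v <- config$domains[[dom]]$re_variances
    for (k in seq_along(.re_names)) {
      truth[[paste0("u", k - 1L, "_", dom)]] <- stats::rnorm(n, 0, sqrt(v[k]))
    }
  }

  start_day <- as.integer(config$start_date)
  types <- c("tap", "scroll", "type", "app_change", "screen_on")
  ev_pid <- vector("list", n)
  ev_sec <- vector("list", n)
  for (i in seq_len(n)) {
    Di <- D[i]
    nb <- 96L * Di
    active <- stats::runif(nb) < config$daytime_activity_prob
    len <- max(1L, as.integer(round(dur[i] * 4)))
    dow <- (start_day + 0:(Di - 1L) + 4L) %% 7L   # 0 = Sunday
    shift <- ifelse(dow %in% c(5L, 6L), config$weekend_onset_shift_h, 0)
    on_d <- onset[i] + stats::rnorm(Di, 0, jit[i]) + shift
    s_d <- as.integer(floor((0:(Di - 1L) * 24 + on_d) * 4))
    idx <- rep(s_d, each = len) + rep.int(0:(len - 1L), Di)
    keep <- idx >= 0L & idx < nb
    active[idx[keep] + 1L] <- FALSE
    if (disr[i] > 0) {
      k_d <- stats::rpois(Di, disr[i])
      K <- sum(k_d)
      if (K > 0L) {
        night <- rep.int(seq_len(Di), k_d)
        dis <- s_d[night] + as.integer(floor(stats::runif(K) * len))
        dis <- dis[dis >= 0L & dis < nb]
        active[dis + 1L] <- TRUE
      }
    }
    if (config$missing_day_prob > 0) {
      miss <- stats::runif(Di) < config$missing_day_prob
      if (any(miss)) active[rep(miss, each = 96L)] <- FALSE
    }
    b <- which(active) - 1L
    ev_pid[[i]] <- rep.int(ids[i], length(b))
    ev_sec[[i]] <- start_day * 86400 + b * 900 + stats::runif(length(b)) * 900
  }
  secs <- unlist(ev_sec)
  events <- data.frame(
    patient_id = unlist(ev_pid),
    timestamp = as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
    event_type = sample(types, length(secs), replace = TRUE),
    stringsAsFactors = FALSE)
  list(events = events, truth = truth, demographics = demo)
}

#' Survey dates implied by a generator configuration
#'
#' Surveys fall every \code{survey_interval_days}, the first one at the end
#' of the first interval, so each has a full run of prior behavior days.
#'
#' @param truth the per-patient truth table from [simulate_events()] (only
#'   \code{patient_id} and \code{n_days} are used).
#' @param config the matching [sim_config()].
#' @return data.frame \code{patient_id}, \code{date}.
#' @export
survey_schedule <- function(truth, config) {
  iv <- config$survey_interval_days
  out <- lapply(seq_len(nrow(truth)), function(i) {
    k <- seq_len(truth$n_days[i] %/% iv)
    data.frame(patient_id = truth$patient_id[i],
               date = config$start_date + k * iv - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# round a clamped continuous domain score to the nearest attainable domain
# mean and expand it into item responses whose mean equals that value
.expand_items <- function(y, items) {
  k <- length(items)
  total <- as.integer(round(y * k))            # 0 .. 4k
  q <- total %/% k
  r <- total %% k
  resp <- matrix(NA_integer_, length(y), k)
  for (j in seq_len(k)) resp[, j] <- q + as.integer(j <= r)
  colnames(resp) <- items
  resp
}

.domain_items <- list(sleep = "sleep",
                      depression = c("anhedonia", "depressed_mood"),
                      anxiety = c("nervous", "panic", "avoidance"))

#' Simulate survey responses from pipeline-computed behavior
#'
#' Phase two of the generator. Outcomes are generated conditional on the
#' behavioral measures the pipeline itself computed, so the generating model
#' and the fitted model share predictors exactly: for every survey occasion
#' the continuous domain score is the fixed-effect linear predictor (using
#' the within/between decomposition from [split_within_between()]) plus the
#' person's random effects and a normal residual, clamped to the 0-4 scale.
#' Item responses are integers whose domain mean equals the clamped score
#' rounded to the instrument's resolution (1 for sleep, 1/2 for depression,
#' 1/3 for anxiety). Occasions flagged as having fewer than the minimum
#' viable prior days are still emitted, with missing responses, since their
#' within-person predictor components are undefined; the modeling pipeline
#' excludes them anyway.
#'
#' @param rows decomposed observation rows from [split_within_between()]
#'   (columns \code{patient_id}, \code{date}, \code{retained},
#'   \code{wp_*}, \code{bp_*}).
#' @param truth,demographics as returned by [simulate_events()].
#' @param config the matching [sim_config()].
#' @return list with \code{items} (long data.frame \code{patient_id},
#'   \code{date}, \code{item_id}, \code{response}) and \code{truth} (per
#'   occasion and domain: linear predictor, continuous clamped outcome,
#'   rounded domain score).
#' @export
simulate_surveys <- function(rows, truth, demographics, config) {
  set.seed(config$seed + 1L)
  ti <- match(rows$patient_id, truth$patient_id)
  di <- match(rows$patient_id, demographics$patient_id)
  demo_mat <- cbind(age = demographics$age[di],
                    gender_male = demographics$gender_male[di],
                    pd_majordep = demographics$pd_majordep[di],
                    pd_personality = demographics$pd_personality[di],
                    pd_schizophrenia = demographics$pd_schizophrenia[di],
                    location_rural = demographics$location_rural[di])
  item_rows <- list()
  truth_rows <- list()
  for (dom in names(config$domains)) {
    d <- config$domains[[dom]]
    g <- d$fixed_effects
    lp <- g["intercept"] +
      g["wp_overlap"] * rows$wp_overlap +
      g["wp_disruption"] * rows$wp_disruption +
      g["wp_duration"] * rows$wp_duration +
      g["bp_overlap"] * rows$bp_overlap +
      g["bp_disruption"] * rows$bp_disruption +
      g["bp_duration"] * rows$bp_duration +
      as.numeric(demo_mat %*% g[colnames(demo_mat)])
    u <- sapply(0:3, function(k) truth[[paste0("u", k, "_", dom)]][ti])
    lp_re <- lp + u[, 1L] + u[, 2L] * rows$wp_overlap +
      u[, 3L] * rows$wp_disruption + u[, 4L] * rows$wp_duration
    y <- lp_re + stats::rnorm(nrow(rows), 0, sqrt(d$resid_variance))
    y <- pmin(pmax(y, 0), 4)
    y[!rows$retained] <- NA_real_
    items <- .domain_items[[dom]]
    resp <- .expand_items(ifelse(is.na(y), 0, y), items)
    resp[is.na(y), ] <- NA_integer_
    for (j in seq_along(items)) {
      item_rows[[length(item_rows) + 1L]] <- data.frame(
        patient_id = rows$patient_id, date = rows$date,
        item_id = items[j], response = resp[, j],
        stringsAsFactors = FALSE)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      patient_id = rows$patient_id, date = rows$date, domain = dom,
      linear_predictor = lp_re, outcome = y,
      score = rowMeans(resp), retained = rows$retained,
      stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, item_rows)
  items <- items[order(items$patient_id, items$date, items$item_id), ]
  rownames(items) <- NULL
  list(items = items, truth = do.call(rbind, truth_rows))
}

#' Simulate a complete synthetic cohort
#'
#' Runs both generator phases end to end: simulate event streams, push them
#' through the package's own binning/measure/aggregation pipeline, and
#' generate survey responses from the resulting within/between predictor
#' components. Because outcomes are conditional on pipeline-computed
#' measures, refitting the model on this cohort recovers the generating
#' coefficients without attenuation from the measurement pipeline.
#'
#' @param config a [sim_config()] object.
#' @param window_len ESP window length in days.
#' @param agg_days length of the pre-survey aggregation window, days.
#' @param min_viable_days minimum viable days for a survey occasion.
#' @return list with \code{events}, \code{truth}, \code{demographics},
#'   \code{activity}, \code{profiles}, \code{measures}, \code{occasions}
#'   (aggregated + decomposed predictor rows), \code{surveys} (long item
#'   responses) and \code{survey_truth}.
#' @export
simulate_cohort <- function(config = sim_config(), window_len = 30L,
                            agg_days = 14L, min_viable_days = 3L) {
  ev <- simulate_events(config)
  activity <- bin_events(ev$events)
  profiles <- window_profiles(activity, window_len)
  measures <- daily_measures(activity, profiles, window_len)
  occ <- aggregate_presurvey(measures, survey_schedule(ev$truth, config),
                             agg_days = agg_days,
                             min_viable_days = min_viable_days)
  occ <- split_within_between(occ)
  sur <- simulate_surveys(occ, ev$truth, ev$demographics, config)
  list(events = ev$events, truth = ev$truth, demographics = ev$demographics,
       activity = activity, profiles = profiles, measures = measures,
       occasions = occ, surveys = sur$items, survey_truth = sur$truth)
}

#' Simulate model-ready observation rows directly
#'
#' A lightweight observation-level generator for studying the estimator
#' itself (calibration, type-I error, power) without running the event
#' pipeline: behavioral aggregates are drawn from a simple person + occasion
#' normal model, decomposed empirically into within/between components, and
#' outcomes generated from the same two-level linear model the package
#' fits. By default the outcome is left unclamped so that null-calibration
#' runs probe the estimator, not the instrument's floor and ceiling;
#' \code{clamp = TRUE} restores the 0-4 bounds.
#'
#' @param n_patients,n_occasions design size.
#' @param fixed_effects,re_variances,resid_variance generating parameters,
#'   as in [sim_config()].
#' @param clamp clamp outcomes to the 0-4 instrument range?
#' @param seed integer seed.
#' @return a model-ready data.frame (patient_id, occasion, outcome columns
#'   named \code{sleep}, wp_/bp_ predictors, demographics).
#' @export
simulate_observation_rows <- function(n_patients = 150L, n_occasions = 6L,
                                      fixed_effects =
                                        .domain_presets$sleep$fixed_effects,
                                      re_variances =
                                        .domain_presets$sleep$re_variances,
                                      resid_variance =
                                        .domain_presets$sleep$resid_variance,
                                      clamp = FALSE, seed = 1L) {
  set.seed(seed)
  g <- .complete_coefs(fixed_effects, .coef_names)
  v <- .complete_coefs(re_variances, .re_names)
  n <- n_patients
  m <- n_occasions
  ids <- sprintf("P%04d", seq_len(n))
  demo <- .simulate_demographics(ids)
  ov_i <- pmin(pmax(stats::rnorm(n, 0.75, 0.12), 0.05), 1)
  di_i <- pmax(stats::rnorm(n, 4.85, 2.0), 0)
  du_i <- pmax(stats::rnorm(n, 8.4, 1.5), 3)
  pid <- rep(ids, each = m)
  k <- rep(seq_len(n), each = m)
  ov <- pmin(pmax(ov_i[k] + stats::rnorm(n * m, 0, 0.07), 0), 1)
  dis <- pmax(di_i[k] + stats::rnorm(n * m, 0, 0.8), 0)
  dur <- du_i[k] + stats::rnorm(n * m, 0, 0.5)
  bp <- function(x) stats::ave(x, pid)
  rows <- data.frame(patient_id = pid, occasion = rep(seq_len(m), n),
                     agg_overlap = ov, agg_disruption = dis,
                     agg_duration = dur, stringsAsFactors = FALSE)
  rows$bp_overlap <- bp(ov)
  rows$bp_disruption <- bp(dis)
  rows$bp_duration <- bp(dur)
  rows$wp_overlap <- ov - rows$bp_overlap
  rows$wp_disruption <- dis - rows$bp_disruption
  rows$wp_duration <- dur - rows$bp_duration
  u <- sapply(v, function(s2) stats::rnorm(n, 0, sqrt(s2)))
  dm <- demo[k, c("age", "gender_male", "pd_majordep", "pd_personality",
                  "pd_schizophrenia", "location_rural")]
  y <- g["intercept"] +
    g["wp_overlap"] * rows$wp_overlap +
    g["wp_disruption"] * rows$wp_disruption +
    g["wp_duration"] * rows$wp_duration +
    g["bp_overlap"] * rows$bp_overlap +
    g["bp_disruption"] * rows$bp_disruption +
    g["bp_duration"] * rows$bp_duration +
    as.numeric(as.matrix(dm) %*% g[colnames(dm)]) +
    u[k, 1L] + u[k, 2L] * rows$wp_overlap + u[k, 3L] * rows$wp_disruption +
    u[k, 4L] * rows$wp_duration +
    stats::rnorm(n * m, 0, sqrt(resid_variance))
  if (clamp) y <- pmin(pmax(y, 0), 4)
  rows$sleep <- y
  cbind(rows, dm, row.names = NULL)
}
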