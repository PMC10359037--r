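# Independent brute-force oracles and small fixture builders used across
# the test files.

# longest all-zero window, non-circular, by exhaustive O(n^2) enumeration;
# earliest start on ties. Returns list(start, length) 0-based, or NULL.
oracle_longest_zero_run <- function(x) {
  n <- length(x)
  cs <- c(0L, cumsum(as.integer(x != 0)))
  best <- NULL
  for (len in n:1) {
    for (s in 1:(n - len + 1)) {
      if (cs[s + len] - cs[s] == 0L) {
        best <- list(start = s - 1L, length = len)
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

# circular variant: maximal zero-run length with the sequence wrapped,
# capped at n. Returns the length only (tie-breaking is checked separately
# against the implementation's stated rule).
oracle_longest_zero_run_circular <- function(x) {
  n <- length(x)
  if (all(x == 0)) return(n)
  y <- c(x, x)
  cs <- c(0L, cumsum(as.integer(y != 0)))
  best <- 0L
  for (s in 1:n) {
    for (len in min(n, 2L * n - s + 1L):1) {
      if (cs[s + len] - cs[s] == 0L) {
        best <- max(best, len)
        break
      }
    }
  }
  best
}

# exhaustive 1-D 2-means: all 95 sorted-order thresholds, minimal
# within-cluster sum of squares. Returns 0/1 assignment (low cluster = 0).
oracle_two_means <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  best_w <- Inf
  best_t <- NA
  for (t in 1:(n - 1)) {
    lo <- xs[1:t]
    hi <- xs[(t + 1):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best_w - 1e-15) {
      best_w <- w
      best_t <- t
    }
  }
  assign <- integer(n)
  assign[o[(best_t + 1):n]] <- 1L
  assign
}

# hand-built day-level activity rows compatible with the pipeline
make_activity <- function(patient_id, dates, bins_list) {
  m <- do.call(rbind, lapply(bins_list, as.integer))
  uah <- apply(m, 1, function(b) {
    sum(vapply(0:23, function(h) any(b[(4 * h + 1):(4 * h + 4)] != 0),
               logical(1)))
  })
  out <- data.frame(patient_id = rep_len(patient_id, nrow(m)),
                    date = dates, stringsAsFactors = FALSE)
  out$bins <- m
  out$unique_active_hours <- as.integer(uah)
  out$adequate <- uah >= 4L
  out
}

# a day with given 0-based active bins
day_bins <- function(active) {
  b <- integer(96)
  b[active + 1L] <- 1L
  b
}

# an adequate day: activity spread over >= 5 clock hours
adequate_day <- function() day_bins(c(40, 44, 48, 52, 56, 60))

# an inadequate day: single active bin
inadequate_day <- function() day_bins(50)

# quick event builder
make_events <- function(patient_id, times, tz = "UTC") {
  data.frame(patient_id = patient_id,
             timestamp = as.POSIXct(times, tz = tz),
             event_type = "tap", stringsAsFactors = FALSE)
}

# a quiet generator configuration: small, deterministic sleep, no noise
quiet_config <- function(...) {
  sim_config(n_patients = 3L, days_per_patient = 40L,
             sleep_onset_mean_h = 1, sleep_onset_sd_h = 0,
             sleep_duration_mean_h = 8, sleep_duration_sd_h = 0,
             onset_jitter_sd_h = 0, onset_jitter_spread_h = 0,
             disruption_rate = 0, disruption_rate_sd = 0,
             missing_day_prob = 0, daytime_activity_prob = 1,
             extra_domains = list(), seed = 1L, ...)
}
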