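# Daily and 30-day sleep measures derived from binary 15-min activity bins.

#' Longest inactive run within a day (inferred sleep period)
#'
#' Scans a day's 96 binary activity bins (bin k covers \code{[15k, 15(k+1))}
#' minutes after local midnight) and returns the longest maximal run of
#' inactive bins, the day-level inferred sleep period (ISP). The scan is
#' non-circular: the day runs from 00:00 to 23:59 and a sleep period that
#' crosses midnight is truncated at the day boundary. Ties are broken in
#' favour of the earliest run.
#'
#' @param bins integer or logical vector of length 96; non-zero means active.
#' @return a list with elements \code{start} (0-based bin index),
#'   \code{length} (bins) and \code{circular = FALSE}, or \code{NULL} when
#'   every bin is active.
#' @seealso [esp_span()] for the circular 30-day analogue.
#' @export
isp_span <- function(bins) {
  if (length(bins) != 96L) stop("'bins' must have length 96")
  act <- as.integer(bins) != 0L
  if (all(act)) return(NULL)
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idle <- which(!r$values)
  best <- idle[which.max(r$lengths[idle])] # which.max keeps the earliest tie
  list(start = starts[best] - 1L, length = as.integer(r$lengths[best]),
       circular = FALSE)
}

# maximal circular runs of TRUE in a logical vector; caller guarantees the
# vector is not constant. Returns 0-based starts.
.circular_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  st <- starts[idx]
  ln <- r$lengths[idx]
  nr <- length(r$values)
  if (length(idx) > 1L && r$values[1L] && r$values[nr]) {
    k <- length(st)                 # merge the wrap-around run
    st[1L] <- st[k]
    ln[1L] <- ln[1L] + ln[k]
    st <- st[-k]
    ln <- ln[-k]
  }
  data.frame(start = st - 1L, length = as.integer(ln))
}

#' Expected sleep period from a binarized 30-day profile
#'
#' Returns the longest run of inactive (0) bins in a binarized 96-bin
#' activity profile, treating the sequence as circular so that a habitual
#' nocturnal period spanning midnight forms a single run. Run length is
#' capped at 96. When several inactive runs tie for the maximum length, the
#' run whose start comes earliest after the end of the longest active run is
#' chosen (and the smallest start index on a further tie), which keeps the
#' result deterministic.
#'
#' @param binarized integer/logical vector of length 96 (1 = habitually
#'   active, 0 = habitually inactive), e.g. from [binarize_fraction()].
#' @return list with \code{start} (0-based), \code{length}, \code{circular}
#'   (TRUE when the run wraps past bin 95), and \code{degenerate} (TRUE when
#'   all 96 bins are inactive); \code{NULL} when no bin is inactive.
#' @export
esp_span <- function(binarized) {
  if (length(binarized) != 96L) stop("'binarized' must have length 96")
  act <- as.integer(binarized) != 0L
  if (all(act)) return(NULL)
  if (!any(act)) {
    return(list(start = 0L, length = 96L, circular = FALSE, degenerate = TRUE))
  }
  zero <- .circular_runs(!act)
  cand <- zero[zero$length == max(zero$length), , drop = FALSE]
  if (nrow(cand) > 1L) {
    arun <- .circular_runs(act)
    ai <- which.max(arun$length)   # earliest longest active run
    aend <- (arun$start[ai] + arun$length[ai]) %% 96L
    dist <- (cand$start - aend) %% 96L
    cand <- cand[order(dist, cand$start), , drop = FALSE]
  }
  start <- cand$start[1L]
  len <- min(cand$length[1L], 96L)
  list(start = start, length = len, circular = start + len > 96L,
       degenerate = FALSE)
}

#' Binarize a per-bin activity-fraction profile by 1-D 2-means
#'
#' Partitions the 96 per-bin fractions of days-with-activity into a low and
#' a high cluster by exact one-dimensional 2-means: the optimal k = 2
#' partition of scalars is a split of the sorted values, so the within-
#' cluster sum of squares is minimised directly over all 95 sorted-order
#' thresholds (via prefix sums), which is k-means clustering converged to
#' its global optimum, deterministically — no random initialisation, no
#' local optima. The lower-mean cluster is labelled inactive (0), the other
#' active (1).
#'
#' @param fractions numeric vector of length 96, values in \code{[0, 1]}.
#' @param tol profiles whose range does not exceed \code{tol} are treated
#'   as constant.
#' @return integer vector of length 96 with values 0/1, or \code{NULL} when
#'   all fractions are identical (no two clusters exist, so no expected
#'   sleep period is derivable).
#' @export
binarize_fraction <- function(fractions, tol = 1e-10) {
  if (length(fractions) != 96L) stop("'fractions' must have length 96")
  x <- as.numeric(fractions)
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("'fractions' must be in [0, 1] with no NA")
  }
  if (diff(range(x)) <= tol) return(NULL)
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs * xs)
  t <- seq_len(n - 1L)
  wcss <- (cs2[t] - cs[t]^2 / t) +
    ((cs2[n] - cs2[t]) - (cs[n] - cs[t])^2 / (n - t))
  tbest <- which.min(wcss)             # earliest split on exact ties
  assign <- integer(n)
  assign[o[(tbest + 1L):n]] <- 1L
  assign
}

#' Bin indices covered by a run span
#'
#' @param span a span as returned by [isp_span()] or [esp_span()].
#' @return 0-based bin indices modulo 96.
#' @export
span_bins <- function(span) {
  (span$start + seq_len(span$length) - 1L) %% 96L
}

#' Overlap fraction between a daily ISP and the window ESP
#'
#' The fraction of the day's inferred-sleep-period bins that fall inside the
#' window's expected sleep period: \code{|bins(ISP) n bins(ESP)| /
#' length(ISP)}. The measure is deliberately naive to duration — a short ISP
#' lying wholly inside the ESP scores 1 — so it tracks the regularity of
#' sleep timing, not of sleep length.
#'
#' @param isp,esp run spans; \code{NULL} propagates to \code{NA}.
#' @return a fraction in \code{[0, 1]}, or \code{NA_real_} when either span
#'   is absent.
#' @export
overlap_pct <- function(isp, esp) {
  if (is.null(isp) || is.null(esp)) return(NA_real_)
  length(intersect(span_bins(isp), span_bins(esp))) / isp$length
}

#' Count disrupted bins inside the expected sleep period
#'
#' Number of the day's active 15-min bins whose indices lie within the
#' window's expected sleep period — a proxy for nocturnal wakefulness.
#'
#' @param bins the day's 96 binary activity values.
#' @param esp the window's ESP span; \code{NULL} gives \code{NA}.
#' @return integer count in \code{[0, length(esp)]}.
#' @export
disruption_count <- function(bins, esp) {
  if (is.null(esp)) return(NA_integer_)
  if (length(bins) != 96L) stop("'bins' must have length 96")
  sum(as.integer(bins)[span_bins(esp) + 1L] != 0L)
}

# vectorised longest-zero-run over the rows of a 0/1 matrix; ties resolved
# to the earliest run. length 0 means no inactive bin.
.row_longest_zero_run <- function(A) {
  n <- nrow(A)
  m <- ncol(A)
  z <- A == 0L
  L <- matrix(0L, n, m)
  L[, 1L] <- as.integer(z[, 1L])
  for (j in 2:m) L[, j] <- (L[, j - 1L] + 1L) * z[, j]
  jmax <- max.col(L, ties.method = "first")
  len <- L[cbind(seq_len(n), jmax)]
  list(start = jmax - len, length = len)
}

#' Per-window activity profiles and expected sleep periods
#'
#' Groups each patient's days into consecutive non-overlapping windows
#' (anchored at the patient's first observed day), computes for every window
#' the per-bin fraction of adequate days with activity, binarizes that
#' profile with [binarize_fraction()] and derives the expected sleep period
#' with [esp_span()]. A window is valid only when the patient's observation
#' span covers all \code{window_len} calendar days of it (trailing partial
#' windows are invalid) and at least half of those days are adequate.
#'
#' @param activity day-level activity as returned by [bin_events()].
#' @param window_len window length in days (30 by default).
#' @return a data.frame with one row per patient-window: \code{patient_id},
#'   \code{window_index} (0-based), \code{n_days}, \code{n_adequate},
#'   \code{complete}, \code{valid}, \code{esp_start}, \code{esp_len},
#'   \code{esp_duration_h}, plus matrix columns \code{fraction} and
#'   \code{binarized} (96 columns each, NA for invalid windows).
#' @export
window_profiles <- function(activity, window_len = 30L) {
  win <- assign_windows(activity, window_len)
  pid <- as.character(activity$patient_id)
  day <- as.integer(activity$date)
  first <- stats::ave(day, pid, FUN = min)
  last <- stats::ave(day, pid, FUN = max)
  span <- last - first + 1L
  key <- paste(pid, win$window_index, sep = "\r")
  grp <- match(key, unique(key))
  ng <- max(grp)

  n_days <- tabulate(grp, ng)
  adq <- activity$adequate
  n_adequate <- as.integer(rowsum(as.integer(adq), grp)[, 1L])
  ord1 <- match(seq_len(ng), grp)      # first row of each group
  out <- data.frame(patient_id = pid[ord1],
                    window_index = win$window_index[ord1],
                    n_days = n_days,
                    n_adequate = n_adequate,
                    stringsAsFactors = FALSE)
  out$complete <- (out$window_index + 1L) * window_len <= span[ord1]
  out$valid <- out$complete & out$n_adequate >= ceiling(window_len / 2)

  bins <- activity$bins
  frac <- matrix(NA_real_, ng, 96L)
  sel <- which(adq)
  if (length(sel)) {
    s <- rowsum(bins[sel, , drop = FALSE], grp[sel])
    gi <- as.integer(rownames(s))
    frac[gi, ] <- s / n_adequate[gi]
  }
  binz <- matrix(NA_integer_, ng, 96L)
  out$esp_start <- NA_integer_
  out$esp_len <- NA_integer_
  for (g in which(out$valid)) {
    b <- binarize_fraction(frac[g, ])
    if (is.null(b)) {
      out$valid[g] <- FALSE          # constant profile: no ESP derivable
      next
    }
    sp <- esp_span(b)
    if (is.null(sp)) {
      out$valid[g] <- FALSE          # no inactive bin at all
      next
    }
    binz[g, ] <- b
    out$esp_start[g] <- sp$start
    out$esp_len[g] <- sp$length
  }
  out$esp_duration_h <- out$esp_len * 0.25
  out$fraction <- frac
  out$binarized <- binz
  out
}

#' Daily behavioral sleep measures
#'
#' Combines day-level activity with window-level expected sleep periods to
#' produce, per patient-day: the inferred sleep period (ISP), the fraction
#' of its bins overlapping the window ESP, the count of disrupted bins
#' inside the ESP, and the ESP duration. A day is viable when it is adequate
#' (activity in at least 4 distinct clock hours), its window is valid, and
#' an ISP exists; overlap and disruption are reported only for viable days.
#'
#' @param activity day-level activity from [bin_events()].
#' @param profiles window profiles from [window_profiles()]; computed when
#'   missing.
#' @param window_len window length in days, must match \code{profiles}.
#' @return data.frame with one row per patient-day: \code{patient_id},
#'   \code{date}, \code{window_index}, \code{adequate}, \code{isp_start},
#'   \code{isp_len}, \code{overlap}, \code{disruptions},
#'   \code{esp_duration_h}, \code{viable}.
#' @export
daily_measures <- function(activity, profiles = NULL, window_len = 30L) {
  if (is.null(profiles)) profiles <- window_profiles(activity, window_len)
  win <- assign_windows(activity, window_len)
  n <- nrow(activity)
  bins <- activity$bins
  run <- .row_longest_zero_run(bins)
  isp_start <- ifelse(run$length > 0L, run$start, NA_integer_)
  isp_len <- ifelse(run$length > 0L, run$length, NA_integer_)

  pkey <- paste(profiles$patient_id, profiles$window_index, sep = "\r")
  dkey <- paste(as.character(activity$patient_id), win$window_index,
                sep = "\r")
  pi <- match(dkey, pkey)
  wvalid <- !is.na(pi) & profiles$valid[pi]
  viable <- activity$adequate & wvalid & !is.na(isp_len)

  overlap <- rep(NA_real_, n)
  disrupt <- rep(NA_integer_, n)
  esp_dur <- rep(NA_real_, n)
  esp_dur[wvalid] <- profiles$esp_duration_h[pi[wvalid]]
  for (g in unique(pi[viable])) {
    mask <- logical(96L)
    mask[span_bins(list(start = profiles$esp_start[g],
                        length = profiles$esp_len[g])) + 1L] <- TRUE
    rows <- which(viable & pi == g)
    disrupt[rows] <- as.integer(bins[rows, mask, drop = FALSE] %*%
                                  rep(1L, sum(mask)))
    cs <- c(0L, cumsum(mask))        # ISPs are contiguous, so a prefix sum
    overlap[rows] <- (cs[isp_start[rows] + isp_len[rows] + 1L] -
                        cs[isp_start[rows] + 1L]) / isp_len[rows]
  }
  data.frame(patient_id = as.character(activity$patient_id),
             date = activity$date,
             window_index = win$window_index,
             adequate = activity$adequate,
             isp_start = isp_start,
             isp_len = isp_len,
             overlap = overlap,
             disruptions = disrupt,
             esp_duration_h = esp_dur,
             viable = viable,
             stringsAsFactors = FALSE)
}
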