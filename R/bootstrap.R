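# ID-level bootstrap: how often would each association be detected on a
# much smaller cohort drawn from the same population?

#' Bootstrap detection power by ID-level resampling
#'
#' Re-estimates the two-level model on repeated random sub-samples: each
#' replicate draws \code{ceiling(sample_frac * n_patients)} patient IDs
#' with replacement and keeps all observations of every drawn ID.
#' Duplicated IDs are relabelled as distinct patients so the grouping
#' structure stays valid for the mixed model. A coefficient counts as
#' detected in a replicate when its Wald p-value is below \code{alpha}
#' and its sign matches the full-data estimate (sign-flipped significance
#' is not credited). Replicates whose refit fails are counted and excluded
#' from the power denominator.
#'
#' @param rows model-ready observation rows.
#' @param outcome outcome column name.
#' @param demographics demographic covariates for the refits.
#' @param n_samples number of bootstrap replicates (500 in the full
#'   procedure; reducible for desk-scale runs).
#' @param sample_frac fraction of patients per replicate.
#' @param alpha detection significance level.
#' @param seed integer seed for the resampling.
#' @param full_fit optional pre-computed full-data \code{symptom_lmm}
#'   (fitted if missing) supplying the reference signs.
#' @param ... further arguments passed to [fit_symptom_model()] for the
#'   replicate fits (influence filtering defaults to "none" inside the
#'   replicates: the full-data filter has already been applied when
#'   \code{rows} comes out of it).
#' @return object of class \code{"bootstrap_power"}: a data.frame with one
#'   row per coefficient (\code{term}, \code{full_estimate},
#'   \code{detection_power}, \code{n_detected}, \code{n_converged}) plus
#'   attributes \code{n_samples}, \code{sample_frac}, \code{n_failures}.
#' @export
bootstrap_power <- function(rows, outcome = "sleep",
                            demographics = .default_demographics,
                            n_samples = 500L, sample_frac = 0.20,
                            alpha = 0.05, seed = 1L, full_fit = NULL, ...) {
  stopifnot(n_samples > 0L, sample_frac > 0, sample_frac <= 1)
  if (is.null(full_fit)) {
    full_fit <- fit_symptom_model(rows, outcome,
                                  demographics = demographics,
                                  influence = "none", ...)
  }
  ref <- coef(full_fit)
  ids <- unique(as.character(rows$patient_id))
  k <- as.integer(ceiling(sample_frac * length(ids)))
  by_id <- split(seq_len(nrow(rows)), as.character(rows$patient_id))

  set.seed(seed)
  detected <- matrix(0L, n_samples, length(ref),
                     dimnames = list(NULL, names(ref)))
  converged <- logical(n_samples)
  for (s in seq_len(n_samples)) {
    draw <- sample(ids, k, replace = TRUE)
    idx <- unlist(by_id[draw], use.names = FALSE)
    sub <- rows[idx, , drop = FALSE]
    # relabel duplicated draws as distinct patients
    sub$patient_id <- rep(paste0(draw, "#", seq_along(draw)),
                          lengths(by_id[draw]))
    fit <- tryCatch(
      fit_symptom_model(sub, outcome, demographics = demographics,
                        influence = "none", ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    converged[s] <- TRUE
    tab <- fit$coefficients
    hit <- tab$p_value < alpha & sign(tab$estimate) == sign(ref[tab$term])
    detected[s, tab$term] <- as.integer(hit)
  }
  ncv <- sum(converged)
  out <- data.frame(term = names(ref),
                    full_estimate = unname(ref),
                    detection_power = colSums(detected[converged, ,
                                                       drop = FALSE]) / ncv,
                    n_detected = colSums(detected[converged, ,
                                                  drop = FALSE]),
                    n_converged = ncv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("bootstrap_power", "data.frame"),
            n_samples = n_samples, sample_frac = sample_frac,
            n_failures = n_samples - ncv, outcome = outcome)
}

#' @export
print.bootstrap_power <- function(x, digits = 3, ...) {
  cat(sprintf("ID-level bootstrap detection power (%s): %d samples of %.0f%% of patients, %d failed\n",
              attr(x, "outcome"), attr(x, "n_samples"),
              100 * attr(x, "sample_frac"), attr(x, "n_failures")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
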