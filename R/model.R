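# Two-level mixed model of symptom severity on behavioral sleep measures,
# with demographic screening, Cook's-distance influence filtering and
# Kolmogorov-Smirnov stability checks.

.wp_bp_terms <- c("wp_overlap", "wp_disruption", "wp_duration",
                  "bp_overlap", "bp_disruption", "bp_duration")

.default_demographics <- c("age", "gender_male", "pd_majordep",
                           "pd_personality", "pd_schizophrenia",
                           "location_rural")

#' Screen demographic covariates against the symptom outcomes
#'
#' Each candidate demographic is regressed independently against each
#' outcome in a random-intercept model (\code{outcome ~ demographic +
#' (1 | patient)}), and is flagged for inclusion when its Wald p-value is
#' below \code{alpha} for at least one outcome. Variables missing in more
#' than \code{max_missing} of observations are excluded before testing
#' (the fate of ethnicity-like variables), as are constants. Multi-level
#' factors are tested with a joint Wald chi-square across their contrasts.
#'
#' @param rows model-ready observation rows (see
#'   [build_observation_rows()]).
#' @param demographics character vector of candidate column names.
#' @param outcomes outcome column names.
#' @param alpha significance level of the inclusion rule.
#' @param max_missing maximum tolerated missingness fraction.
#' @return list with \code{table} (variable x outcome estimates and
#'   p-values), \code{included} (character vector) and \code{excluded}
#'   (named character vector of reasons).
#' @export
screen_demographics <- function(rows,
                                demographics = .default_demographics,
                                outcomes = c("sleep", "depression",
                                             "anxiety"),
                                alpha = 0.05, max_missing = 0.30) {
  outcomes <- intersect(outcomes, names(rows))
  tab <- list()
  excluded <- character()
  for (v in demographics) {
    x <- rows[[v]]
    if (is.null(x)) {
      excluded[v] <- "not present"
      next
    }
    if (mean(is.na(x)) > max_missing) {
      excluded[v] <- sprintf("missingness %.0f%% exceeds %.0f%%",
                             100 * mean(is.na(x)), 100 * max_missing)
      next
    }
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning(sprintf("demographic '%s' is constant; excluded", v))
      excluded[v] <- "constant"
      next
    }
    for (oc in outcomes) {
      d <- rows[!is.na(rows[[oc]]) & !is.na(x), , drop = FALSE]
      f <- stats::as.formula(paste0(oc, " ~ ", v, " + (1 | patient_id)"))
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(f, data = d, REML = TRUE)))
      b <- lme4::fixef(fit)
      V <- as.matrix(stats::vcov(fit))
      ii <- setdiff(seq_along(b), 1L)       # all non-intercept contrasts
      if (length(ii) == 1L) {
        z <- b[ii] / sqrt(V[ii, ii])
        p <- 2 * stats::pnorm(-abs(z))
      } else {
        W <- as.numeric(t(b[ii]) %*% solve(V[ii, ii]) %*% b[ii])
        p <- stats::pchisq(W, df = length(ii), lower.tail = FALSE)
      }
      tab[[length(tab) + 1L]] <- data.frame(
        variable = v, outcome = oc, estimate = unname(b[ii][1L]),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(tab)) do.call(rbind, tab) else
    data.frame(variable = character(), outcome = character(),
               estimate = numeric(), p_value = numeric())
  inc <- tapply(tab$p_value < alpha, tab$variable, any)
  included <- names(inc)[inc]
  tab$included <- tab$variable %in% included
  list(table = tab, included = included, excluded = excluded)
}

#' Remove influential observations by the Cook's-distance rule
#'
#' Fits a pooled least-squares regression of the outcome on the six
#' within/between behavioral predictors (no demographics, no random
#' effects: per-observation Cook's distance is classically defined for a
#' fixed-effects regression) and removes observations whose Cook's distance
#' exceeds \code{multiplier} times a baseline. The baseline is the mean
#' Cook's distance over observations (\code{"mean"}, the common influence
#' heuristic) or \code{4/n} (\code{"4n"}); the phrase "four times Cook's
#' distance" is ambiguous, so both are exposed.
#'
#' @param rows model-ready observation rows.
#' @param outcome outcome column name.
#' @param multiplier threshold multiplier.
#' @param baseline \code{"mean"} or \code{"4n"}.
#' @return list with \code{retained} (rows below threshold, outcome
#'   non-missing), \code{removed} (rows above), \code{removed_fraction},
#'   \code{threshold} and \code{cooks} (the distances).
#' @export
cooks_filter <- function(rows, outcome, multiplier = 4,
                         baseline = c("mean", "4n")) {
  baseline <- match.arg(baseline)
  d <- rows[!is.na(rows[[outcome]]), , drop = FALSE]
  for (v in .wp_bp_terms) d <- d[!is.na(d[[v]]), , drop = FALSE]
  if (nrow(d) < 10L) stop("need at least 10 complete observations")
  # constant predictors carry no leverage information; drop them rather
  # than fail (a fully degenerate data set removes nothing)
  terms <- .wp_bp_terms[vapply(.wp_bp_terms,
                               function(v) stats::var(d[[v]]) > 0,
                               logical(1L))]
  f <- stats::as.formula(paste0(outcome, " ~ ",
                                if (length(terms))
                                  paste(terms, collapse = " + ") else "1"))
  lmfit <- stats::lm(f, data = d)
  alias <- is.na(stats::coef(lmfit))
  if (any(alias)) {
    stop("singular design; collinear column(s): ",
         paste(names(stats::coef(lmfit))[alias], collapse = ", "))
  }
  if (stats::sigma(lmfit) < 1e-9) {        # perfect fit: no influence
    D <- rep(0, nrow(d))
  } else {
    D <- stats::cooks.distance(lmfit)
  }
  thr <- if (baseline == "mean") multiplier * mean(D) else
    multiplier / nrow(d)
  drop <- D > thr
  list(retained = d[!drop, , drop = FALSE],
       removed = d[drop, , drop = FALSE],
       removed_fraction = mean(drop),
       threshold = thr,
       cooks = D)
}

#' Compare variable distributions before and after cleaning
#'
#' Two-sample Kolmogorov-Smirnov tests between the pre- and post-filter
#' distributions of the outcome and each behavioral predictor, verifying
#' that influence filtering did not materially change the data.
#'
#' @param before,after data.frames holding the same columns.
#' @param vars columns to compare.
#' @return data.frame \code{variable}, \code{statistic}, \code{p_value}.
#' @export
ks_compare <- function(before, after, vars = NULL) {
  if (!nrow(before) || !nrow(after)) stop("both sets must be non-empty")
  if (is.null(vars)) vars <- intersect(names(before), names(after))
  vars <- vars[vapply(before[vars], is.numeric, logical(1L))]
  out <- lapply(vars, function(v) {
    x <- before[[v]]
    y <- after[[v]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    data.frame(variable = v, statistic = unname(kt$statistic),
               p_value = kt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the two-level symptom model
#'
#' The central estimator: a linear mixed model of one symptom domain score
#' on the six within/between behavioral components plus screened
#' demographic covariates, with a random intercept and mutually independent
#' random slopes for the three within-person predictors, estimated by
#' restricted maximum likelihood via \pkg{lme4}. Inference on fixed effects
#' uses Wald z statistics (deterministic and portable; degrees-of-freedom
#' corrections such as Satterthwaite would be slightly more conservative at
#' small n). By default observations failing the Cook's-distance rule are
#' removed first (see [cooks_filter()]) and the before/after distributions
#' are compared with [ks_compare()]. Rows with a missing outcome or missing
#' predictors are dropped (missing at random).
#'
#' If the optimizer fails to converge, the model is refitted with the
#' boundary random slopes (estimated variance ~ 0) removed, and the refit
#' is flagged in the result.
#'
#' @param data model-ready observation rows (one row per survey occasion;
#'   see [build_observation_rows()] or [simulate_observation_rows()]).
#' @param outcome name of the outcome column ("sleep", "depression" or
#'   "anxiety" in pipeline output).
#' @param demographics demographic covariates to adjust for, e.g. the
#'   \code{included} set from [screen_demographics()]. Use
#'   \code{character()} for an unadjusted model.
#' @param influence \code{"cooks"} (default) to apply the influence filter
#'   before fitting, \code{"none"} to fit on all rows.
#' @param cooks_multiplier,cooks_baseline threshold rule passed to
#'   [cooks_filter()].
#' @param random_slopes include the three within-person random slopes?
#' @param reml fit by REML (TRUE) or ML.
#' @param conf_level confidence level of the Wald intervals.
#' @return an object of class \code{"symptom_lmm"}; see
#'   [summary.symptom_lmm()]. Components include \code{coefficients} (the
#'   fixed-effect table), \code{varcomp} (random-effect and residual
#'   variances), \code{fit} (the underlying \code{lmerMod}),
#'   \code{removed_fraction} and \code{ks}.
#' @examples
#' rows <- simulate_observation_rows(n_patients = 60, n_occasions = 4,
#'                                   seed = 7)
#' m <- fit_symptom_model(rows, "sleep", influence = "none")
#' coef(m)["bp_overlap"]
#' @export
fit_symptom_model <- function(data, outcome = "sleep",
                              demographics = .default_demographics,
                              influence = c("cooks", "none"),
                              cooks_multiplier = 4,
                              cooks_baseline = "mean",
                              random_slopes = TRUE,
                              reml = TRUE,
                              conf_level = 0.95) {
  influence <- match.arg(influence)
  cl <- match.call()
  keep <- !is.na(data[[outcome]])
  for (v in .wp_bp_terms) keep <- keep & !is.na(data[[v]])
  for (v in demographics) keep <- keep & !is.na(data[[v]])
  d0 <- data[keep, , drop = FALSE]
  n_before <- nrow(d0)

  removed_fraction <- 0
  ks <- NULL
  if (influence == "cooks") {
    cf <- cooks_filter(d0, outcome, multiplier = cooks_multiplier,
                       baseline = cooks_baseline)
    ks <- ks_compare(d0, cf$retained, vars = c(outcome, .wp_bp_terms))
    removed_fraction <- cf$removed_fraction
    d <- cf$retained
  } else {
    d <- d0
  }

  slopes <- if (random_slopes) c("wp_overlap", "wp_disruption",
                                 "wp_duration") else character()
  fml <- .model_formula(outcome, demographics, slopes)
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = reml),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  dropped <- character()
  if (any(grepl("failed to converge", msgs)) && length(slopes)) {
    vc <- .varcomp(fit)
    near0 <- slopes[vc[slopes] < 1e-6]
    if (length(near0)) {
      dropped <- near0
      slopes <- setdiff(slopes, near0)
      fml <- .model_formula(outcome, demographics, slopes)
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = d, REML = reml)))
      msgs <- c(msgs, sprintf("refit without boundary slope(s): %s",
                              paste(near0, collapse = ", ")))
    }
  }

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = names(b), estimate = unname(b),
                      std_error = unname(se), z_value = unname(z),
                      p_value = unname(p),
                      ci_lower = unname(b - q * se),
                      ci_upper = unname(b + q * se),
                      stringsAsFactors = FALSE)
  vc <- .varcomp(fit)
  structure(list(call = cl, outcome = outcome, formula = fml,
                 coefficients = coefs, varcomp = vc,
                 fit = fit,
                 n_obs = nrow(d),
                 n_patients = length(unique(d$patient_id)),
                 n_removed = n_before - nrow(d),
                 removed_fraction = removed_fraction,
                 ks = ks,
                 demographics = demographics,
                 random_slopes = slopes,
                 dropped_slopes = dropped,
                 messages = msgs,
                 conf_level = conf_level,
                 data = d),
            class = "symptom_lmm")
}

.model_formula <- function(outcome, demographics, slopes) {
  rhs <- c(.wp_bp_terms, demographics, "(1 | patient_id)",
           sprintf("(0 + %s | patient_id)", slopes))
  stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

# named variance components: intercept, each random slope, residual
.varcomp <- function(fit) {
  vc <- lme4::VarCorr(fit)
  out <- c()
  for (nm in names(vc)) {
    m <- vc[[nm]]
    lab <- rownames(m)
    lab[lab == "(Intercept)"] <- "intercept"
    out[lab] <- diag(m)
  }
  out["residual"] <- attr(vc, "sc")^2
  out
}

#' @export
print.symptom_lmm <- function(x, digits = 4, ...) {
  cat("Two-level symptom model (REML via lme4)\n")
  cat("Outcome:", x$outcome, "\n")
  cat(sprintf("Observations: %d (%d patients; %d removed by influence rule, %.2f%%)\n",
              x$n_obs, x$n_patients, x$n_removed,
              100 * x$removed_fraction))
  cat("\nFixed effects:\n")
  tab <- x$coefficients
  cm <- cbind(Estimate = tab$estimate, `Std.Error` = tab$std_error,
              `z value` = tab$z_value, `Pr(>|z|)` = tab$p_value)
  rownames(cm) <- tab$term
  printCoefmat(cm, digits = digits, P.values = TRUE, has.Pvalue = TRUE,
               signif.stars = TRUE, cs.ind = 1:2, tst.ind = 3)
  cat("\nVariance components:\n")
  print(round(x$varcomp, 4))
  if (length(x$dropped_slopes)) {
    cat("\nNote: random slope(s) dropped at boundary:",
        paste(x$dropped_slopes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise a fitted symptom model
#'
#' @param object a \code{symptom_lmm} fit.
#' @param ... unused.
#' @return a list with the coefficient table (estimates, standard errors,
#'   Wald z, p-values and confidence limits), variance components and
#'   sample sizes, of class \code{"summary.symptom_lmm"}.
#' @export
summary.symptom_lmm <- function(object, ...) {
  structure(list(outcome = object$outcome,
                 coefficients = object$coefficients,
                 varcomp = object$varcomp,
                 n_obs = object$n_obs,
                 n_patients = object$n_patients,
                 removed_fraction = object$removed_fraction,
                 ks = object$ks),
            class = "summary.symptom_lmm")
}

#' @export
print.summary.symptom_lmm <- function(x, digits = 4, ...) {
  cat("Outcome:", x$outcome, "\n\n")
  print(x$coefficients, digits = digits, row.names = FALSE)
  cat("\nVariance components:\n")
  print(round(x$varcomp, 4))
  if (!is.null(x$ks)) {
    cat("\nKS stability check (pre vs post influence filtering):\n")
    print(x$ks, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.symptom_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.symptom_lmm <- function(object, ...) as.matrix(stats::vcov(object$fit))

#' @export
confint.symptom_lmm <- function(object, parm, level = 0.95, ...) {
  b <- coef(object)
  se <- object$coefficients$std_error
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(b - q * se, b + q * se)
  dimnames(ci) <- list(names(b),
                       sprintf("%.1f %%", c((1 - level) / 2,
                                            1 - (1 - level) / 2) * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.symptom_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...) else
    stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.symptom_lmm <- function(object, ...) {
  stats::residuals(object$fit, ...)
}

#' @export
fitted.symptom_lmm <- function(object, ...) stats::fitted(object$fit)

#' @export
nobs.symptom_lmm <- function(object, ...) object$n_obs

#' @export
simulate.symptom_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Diagnostic plots for a fitted symptom model
#'
#' Residuals versus fitted values and a normal Q-Q plot of the
#' (conditional) residuals.
#'
#' @param x a \code{symptom_lmm} fit.
#' @param which subset of \code{1:2}.
#' @param ... passed to the underlying plot calls.
#' @export
plot.symptom_lmm <- function(x, which = 1:2, ...) {
  r <- stats::residuals(x$fit)
  if (1 %in% which) {
    plot(stats::fitted(x$fit), r, xlab = "Fitted values",
         ylab = "Residuals",
         main = paste("Residuals vs fitted:", x$outcome), ...)
    graphics::abline(h = 0, lty = 2)
  }
  if (2 %in% which) {
    stats::qqnorm(r, main = paste("Normal Q-Q:", x$outcome), ...)
    stats::qqline(r)
  }
  invisible(x)
}

#' Run the full association analysis for every outcome
#'
#' Screens demographics, then fits the two-level model (with influence
#' filtering and KS stability checks) for each outcome using the screened
#' covariate set.
#'
#' @param rows model-ready observation rows.
#' @param outcomes outcome column names.
#' @param demographics candidate demographic columns for screening.
#' @param ... passed to [fit_symptom_model()].
#' @return list with \code{screening} and \code{fits} (one
#'   \code{symptom_lmm} per outcome).
#' @export
run_association_analysis <- function(rows,
                                     outcomes = c("sleep", "depression",
                                                  "anxiety"),
                                     demographics = .default_demographics,
                                     ...) {
  scr <- screen_demographics(rows, demographics, outcomes)
  fits <- lapply(outcomes, function(oc) {
    fit_symptom_model(rows, oc, demographics = scr$included, ...)
  })
  names(fits) <- outcomes
  list(screening = scr, fits = fits)
}
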