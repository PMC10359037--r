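---
title: "Behavioral sleep measures from passive smartphone data: methods"
author: "sleeptrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral sleep measures from passive smartphone data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeptrace)
```

## The problem

People interact with their phones except, mostly, while they sleep. For a
patient population receiving virtual mental-health care, the timing of
passively recorded human–smartphone interactions (taps, scrolls, typing,
app changes, screen-on events) is therefore a cheap, unobtrusive behavioral
signal about sleep: when the nightly gap in interactions starts, how stable
its timing is from day to day, and how often it is interrupted. This
package implements a full analysis chain from raw event streams to the
question that motivates it: are behavioral sleep measures associated with
self-reported sleep disturbance, depression and anxiety, both when a person
differs from other people and when a person deviates from their own
routine?

## From events to measures

**Binning.** Each patient-day is a sequence of 96 binary 15-minute bins
(bin $k$ covers $[15k, 15(k+1))$ minutes after local midnight); a bin is
active iff at least one event starts inside it. Days with activity in
fewer than 4 distinct clock hours are *inadequate* and never contribute to
measures; patients need at least 28 adequate days to be retained. Days
with no events at all are emitted as all-inactive rows and fail the
adequacy rule, so they follow the same filtering path as sparse days.

**Inferred sleep period (ISP).** The longest maximal run of inactive bins
within a single calendar day, found by run-length encoding, with ties
broken to the earliest run. The day scan is deliberately non-circular
(00:00–23:59): a sleep period crossing midnight is truncated at the day
boundary. This truncation bias is a property of the published measure and
is documented, not corrected.

**Expected sleep period (ESP).** Days are grouped into consecutive,
non-overlapping 30-day windows anchored at each patient's first observed
day. A window is valid only if the patient's span covers all 30 of its
calendar days (trailing partial windows are invalid — the 15-day rule
below has no meaningful rescaling for short windows) and at least 15 of
those days are adequate. For a valid window, the per-bin fraction of
adequate days with activity is binarized into habitually-active (1) and
habitually-inactive (0) bins, and the ESP is the longest inactive run of
the binarized profile treated *circularly*, so a habitual nocturnal period
spanning midnight forms one run. When several inactive runs tie, the run
starting earliest after the end of the longest active run wins — the
"night after the day", deterministically.

**Binarization.** The 96 activity fractions are split into two clusters by
exact one-dimensional 2-means. For scalars the optimal $k=2$ partition is
a split of the sorted values, so the within-cluster sum of squares is
minimized directly over all 95 sorted-order thresholds using prefix sums.
This is the global optimum of the k-means objective, reached
deterministically: iterative Lloyd refinement from heuristic seeds can
stall in a local optimum on weakly bimodal profiles (we verified such
counterexamples against a brute-force oracle), and a measure definition
should not depend on which local optimum an iterative scheme happens to
find. A window whose 96 fractions are all identical has no two clusters
and yields no ESP; the window is marked invalid. Clustering is fit per
window, not pooled per person, so the expected period can track a shifting
routine month by month; this is an interpretation choice where the
published description is ambiguous.

**Overlap percentage.** The fraction of the day's ISP bins lying inside
the window's ESP, $|\mathrm{ISP} \cap \mathrm{ESP}| / |\mathrm{ISP}|$,
with bin sets taken modulo 96. It is deliberately naive to duration: a
short nap-length ISP wholly inside the ESP scores 100%. It is a proxy for
the *timing regularity* of sleep, not its length.

**Disruptions.** The count of the day's active bins inside the ESP — a
proxy for nocturnal wakefulness (or at least for definite phone use during
the habitual sleep window).

A day is *viable* when it is adequate, its window is valid, and an ISP
exists; overlap and disruptions are defined only for viable days.

## From measures to observations

Surveys score three DSM-5 Level 1 domains on the 0–4 Likert scale: sleep
disturbance (one item), depression (mean of two items), anxiety (mean of
three). A domain with any missing item is absent for that survey; other
domains are unaffected.

Each survey occasion is paired with the mean overlap, disruption count and
ESP duration over viable days in the 14 calendar days ending the day
*before* the survey. The survey day itself is excluded: the instrument
asks about the past two weeks, and same-day behavior postdates part of the
recall window (the published procedure does not state this either way; we
document it as an interpretation). Occasions with fewer than 3 viable days
are dropped.

Each behavioral aggregate $x_{it}$ is split into a between-person
component $\mathrm{bp}.x_i$ (the person's mean over their retained
occasions — retained, because that is all a model fit on retained rows can
see) and a within-person component
$\mathrm{wp}.x_{it} = x_{it} - \mathrm{bp}.x_i$, which averages to zero
within each person by construction. Overlap enters the models as a 0–1
fraction: the published between-person coefficient magnitudes on a 0–4
outcome are only plausible on the unit scale.

## The two-level model

For outcome $y_{it}$ (one model per domain):

$$y_{it} = \beta_{0i} + \beta_{1i}\,\mathrm{wp.Overlap}_{it}
         + \beta_{2i}\,\mathrm{wp.Disruption}_{it}
         + \beta_{3i}\,\mathrm{wp.Duration}_{it} + e_{it}$$

$$\beta_{0i} = \gamma_{00} + \gamma_{01}\mathrm{bp.Overlap}_i
  + \gamma_{02}\mathrm{bp.Disruption}_i + \gamma_{03}\mathrm{bp.Duration}_i
  + \boldsymbol\gamma_{04..09}^\top \mathbf{z}_i + u_{0i},
  \qquad \beta_{ki} = \gamma_{k0} + u_{ki},\; k = 1,2,3$$

with $\mathbf{z}_i$ the demographic covariates (age in uncentered years;
male vs female; primary-diagnosis indicators for major depression,
personality disorder, schizophrenia; rural vs urban), $u_{0i},\dots,u_{3i}$
independent mean-zero normals and $e_{it}$ normal residuals. The model is
estimated by REML via `lme4::lmer` with a random intercept and independent
random slopes — variances only, no covariances, matching the reported
parameterization. Fixed-effect inference uses Wald $z$ statistics:
deterministic and portable; Satterthwaite-type corrections would be
slightly more conservative at small cluster counts and are noted here as
the alternative. Outcomes are modeled as continuous despite the 0–4
bounds, as published.

**Demographic screening.** Each candidate demographic is regressed
independently against each outcome in a random-intercept model and kept if
$p < 0.05$ for at least one outcome (a union rule whose family-wise
inclusion rate under the null is correspondingly above 5%). Variables
missing in more than 30% of observations are excluded before testing;
whether the published screening regressions were pooled or mixed is
unstated, and we chose mixed with a random intercept.

**Influence filtering.** Before fitting, a pooled least-squares regression
of the outcome on the six wp/bp predictors (no demographics, no random
effects — per-observation Cook's distance is classically defined for
fixed-effects regression, and the published procedure describes "an
initial regression") provides Cook's distances; observations with
$D_i > 4 \bar D$ are removed. The phrase "four times Cook's distance" is
ambiguous about the baseline, so both the multiplier and the baseline
($\bar D$ or $4/n$) are exposed as arguments. On clean simulated data with
normal residuals this rule removes about 6% of observations. Two-sample
Kolmogorov–Smirnov tests on the outcome and each predictor verify that
filtering leaves the distributions essentially unchanged.

**Bootstrap detection power.** The model is re-estimated on repeated
samples of 20% of the patient IDs drawn with replacement, keeping all
rows of each drawn ID; duplicated IDs are relabelled as distinct patients
so the grouping structure stays valid (the published procedure is silent
on duplicates). A coefficient is detected when $p < 0.05$ *and* its sign
matches the full-data estimate — sign-flipped significance is not credited
(whether the published "agreement" conditioned on sign is unstated).
Detection power is the detected fraction among converged replicates.
Because all replicates resample one cohort, a single cohort's null power
is itself random (it inherits the cohort's chance full-data estimate);
calibration statements should average over generated cohorts, and the
package's tests do.

## The synthetic cohort generator

The generator exists so that every stage is testable against known ground
truth without any private clinical data. It is **two-phase**:

1. **Events.** Each patient gets a habitual onset time, sleep duration,
   day-to-day onset-jitter SD and nightly disruption rate (all drawn from
   population distributions), plus demographics with realistic marginal
   frequencies. Nights are placed on a continuous timeline, so sleep
   crossing midnight genuinely stresses the day-slicing code; bins outside
   sleep are active with a daytime probability, disruption bins inside
   sleep are hit by a Poisson process, whole days go missing at random,
   and every active bin emits an event at a uniform time within it.
2. **Outcomes.** The events are pushed through the package's own
   binning/measure/aggregation pipeline, and survey outcomes are generated
   from the two-level model above *conditional on the pipeline-computed
   wp/bp components*, then clamped to the 0–4 scale and rounded to the
   instrument's attainable resolution (1, 1/2, 1/3 for the three domains)
   by item responses whose domain mean equals the rounded score.

Two-phase generation means the generating model and the fitted model share
predictors exactly, so coefficient recovery is exact in expectation and is
not attenuated by measurement error in the pipeline — which is precisely
what makes it a sharp test of the estimator. The real joint distribution
of measure noise and outcome noise in the clinical cohort is unknown; the
generator's noise model is an explicit assumption stated in its
configuration, not a claim about the cohort.

**Default conditions.** The outcome parameters default to the published
multilevel estimates for the three domains (e.g. for sleep disturbance:
intercept 2.49; wp overlap −0.21, wp disruption 0.045, wp duration −0.03;
bp overlap −0.90, bp disruption 0.098, bp duration 0.015; intercept
variance 0.97, residual variance 0.67). The behavioral parameters were
calibrated once so that the *measured* moments on generated data match the
reference cohort's published descriptives — mean overlap in the mid-70s%,
mean disruptions ≈ 4.85 (SD ≈ 3), mean ESP duration ≈ 8.3–8.4 h (SD ≈
2.3) — and then frozen. The latent values (onset 23:30 ± 1 h across
persons; duration 8.8 ± 1.5 h; onset jitter SD 2.2 ± 1.1 h; nightly
disruption rate 3.0 ± 1.5; daytime activity probability 0.45; missing-day
probability 0.10) differ from the measured targets because the measures
are imperfect: jitter blurs the ESP edges and shortens it, and jittered
daytime activity spills into the ESP and inflates the disruption count
above the latent rate. An optional weekend onset shift (default 0) adds
weekday/weekend structure for the post hoc contrast; no other employment
structure, nap behavior or app-level content is emulated.

What passing tests on this generator do *not* show: robustness to
non-normal outcome noise, informative missingness, timezone churn or
travel, shift work with multi-modal sleep, or measurement regimes where
the phone is simply off. Those belong to the limitations of the measures
themselves.

```{r generator, eval = FALSE}
co <- simulate_cohort(sim_config(n_patients = 50, seed = 1))
rows <- build_observation_rows(co$measures, co$surveys, co$demographics)
fit_symptom_model(rows, "sleep")
```

## Numerical choices and degenerate inputs

* ISP ties → earliest run (published rule unstated; determinism required).
  ESP ties → earliest start after the longest active run, then smallest
  start index.
* A day with all 96 bins inactive has ISP = the whole day; a day with all
  bins active has no ISP and is not viable.
* An all-inactive binarized profile yields a degenerate full-day ESP
  (flagged); such windows cannot arise from valid data because adequacy
  requires activity. An all-active profile yields no ESP.
* Constant activity-fraction profiles (no two clusters) invalidate the
  window rather than fabricate an ESP.
* Exact ties in the threshold scan of the binarization resolve to the
  earliest sorted-order split.
* The 28 adequate days required per patient need not be consecutive (the
  published criterion does not say; we did not guess "consecutive").
* Day boundaries follow the clock labels of one configured timezone; on
  DST transitions duplicated/skipped clock labels are OR-ed into their
  bins. No timezone inference is attempted.
* In the influence filter, constant predictors are dropped (a fully
  degenerate data set removes nothing) and a perfect fit (residual SD
  below 1e−9) yields all-zero distances; genuinely collinear non-constant
  designs raise an error naming the columns.
* If the mixed-model optimizer fails to converge, random slopes whose
  estimated variance is at the zero boundary are dropped and the refit is
  flagged in the result. Singular fits (slope variances estimated at zero)
  are reported as such, not hidden — with within-person predictor
  variation on the scales above, slope variances of order 0.001–0.3 are
  often not identifiable, and their omission moves fixed effects by less
  than one standard error.

## Problem sizes

The package's validation runs use sizes chosen to make the statistics
sharp while staying desk-scale: structural oracles on 10,000 random days
and 1,000 random windows; coefficient recovery on 20 replicates of 300
patients × 8 surveys (~2,350 observations each), asserting mean bias
below twice the mean standard error for every fixed effect of interest;
null calibration on 40 direct observation-level simulations; bootstrap
calibration at three effect sizes averaged over four generated cohorts
with 25 resamples each. The full suite and the acceptance script each run
in a few minutes on one CPU.

## Known limitations

* Smartphone inactivity is not sleep: the ISP misses phone-free
  wakefulness, and a phone left charging overnight in another room
  produces a perfect-looking sleep period.
* The daily ISP is truncated at midnight by definition, biasing daily
  overlap downward for late sleepers; the ESP (circular) is not.
* Overlap is undefined on non-viable days and duration-naive by design.
* The linear model treats a bounded, discretized 0–4 score as continuous;
  the generator's clamping to the instrument range consequently attenuates
  recovered coefficients slightly relative to their generating values (the
  recovery tests measure exactly this attenuation and bound it).
* One timezone per cohort; travel and DST are handled by clock labels
  only.
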