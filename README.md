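# sleeptrace

Behavioral sleep measures from passively sensed human–smartphone
interaction data, and their associations with self-reported mental-health
symptoms.

## What it does, and for whom

People rarely touch their phones while asleep. For cohorts under virtual
behavioral-health care — where raw interaction events (taps, scrolls,
typing, app changes, screen-on) are already collected — the nightly gap in
those events is a free behavioral signal about sleep. `sleeptrace` turns
timestamped event streams into four measures and models their relationship
with self-reported symptoms; it is aimed at digital-phenotyping and
behavioral-sleep researchers who need the whole chain, from raw events to
mixed-model inference, reproducible and testable.

The measures, per patient:

* **ISP** (inferred sleep period): each day's longest run of inactive
  15-minute bins (of the day's 96), found by run-length encoding.
* **ESP** (expected sleep period): for each non-overlapping 30-day window,
  the per-bin fraction of adequate days with activity is binarized by
  exact 1-D 2-means (global within-cluster-sum-of-squares optimum over
  sorted-order thresholds), and the ESP is the longest inactive run of the
  binarized profile treated circularly — the habitual sleep window.
* **Overlap percentage**: |ISP ∩ ESP| / |ISP| — a duration-naive proxy for
  the regularity of sleep *timing*.
* **Disruptions**: the count of active bins inside the ESP — nocturnal
  wakefulness expressed through the phone.

Adequacy filters: a day counts only with activity in ≥ 4 distinct clock
hours; patients need ≥ 28 adequate days; a window is valid with ≥ 15
adequate days out of its full 30.

Survey occasions (DSM-5 Level 1 domains: sleep disturbance, depression,
anxiety, each scored 0–4) are paired with 14-day pre-survey behavioral
aggregates, split into between-person (bp, person mean) and within-person
(wp, occasion deviation) components, and modeled per domain with the
two-level linear mixed model

    y_it = γ00 + γ10·wp.Overlap_it + γ20·wp.Disruption_it + γ30·wp.Duration_it
         + γ01·bp.Overlap_i + γ02·bp.Disruption_i + γ03·bp.Duration_i
         + γ'·demographics_i + u_0i + u_1i·wp.Overlap_it
         + u_2i·wp.Disruption_it + u_3i·wp.Duration_it + e_it

fitted by REML (`lme4`), after demographic screening and removal of
observations exceeding four times the mean Cook's distance in an initial
pooled regression, with Kolmogorov–Smirnov checks that the removal did not
change the distributions, and with ID-level bootstrap detection power
(500 resamples of 20% of patients) for every coefficient.

A two-phase synthetic cohort generator (`simulate_cohort()`) produces
event streams with known ground truth and survey outcomes generated from
the pipeline's own computed predictors, so every stage — and the whole
chain — is testable without any clinical data.

## Worked example

```r
library(sleeptrace)

co   <- simulate_cohort(sim_config(n_patients = 100,
                                   days_per_patient = 180, seed = 42))
rows <- build_observation_rows(co$measures, co$surveys, co$demographics)

vi <- co$measures[co$measures$viable, ]
cat(sprintf("overlap %.2f  disruptions %.2f  esp %.2f h\n",
    mean(vi$overlap), mean(vi$disruptions), mean(vi$esp_duration_h)))
#> overlap 0.75  disruptions 4.30  esp 7.59 h

fit_symptom_model(rows, "sleep")
#> Two-level symptom model (REML via lme4)
#> Outcome: sleep
#> Observations: 555 (100 patients; 29 removed by influence rule, 4.97%)
#>
#> Fixed effects:
#>                   Estimate Std.Error z value Pr(>|z|)
#> (Intercept)       3.963342  0.766375   5.172 2.32e-07 ***
#> wp_overlap       -0.593451  0.462308  -1.284   0.1993
#> wp_disruption    -0.039988  0.059031  -0.677   0.4981
#> wp_duration       0.039233  0.073014   0.537   0.5910
#> bp_overlap       -0.760258  0.924693  -0.822   0.4110
#> bp_disruption     0.025449  0.091503   0.278   0.7809
#> bp_duration      -0.120192  0.093686  -1.283   0.1995
#> age              -0.009445  0.006961  -1.357   0.1748
#> gender_male      -0.162640  0.189745  -0.857   0.3914
#> pd_majordep       0.123050  0.167702   0.734   0.4631
#> pd_personality    0.789953  0.565747   1.396   0.1626
#> pd_schizophrenia -0.888280  0.384008  -2.313   0.0207 *
#> location_rural   -0.155281  0.163789  -0.948   0.3431
#>
#> Variance components:
#>     intercept    wp_overlap wp_disruption   wp_duration      residual
#>        0.4992        0.0000        0.0000        0.0000        0.5690
```

The synthetic cohort's measured moments (overlap 0.75, disruptions 4.3,
ESP 7.6 h) sit near the generator's calibration targets. At 100 patients
the individual coefficient estimates are noisy — the between-person
overlap coefficient here is −0.76 with a standard error of 0.92 against a
generating value of −0.90 — which is exactly the sample-size story the
bootstrap-power machinery quantifies; the package's acceptance run below
uses 20 replicates of 300 patients. The influence rule removed 4.97% of
observations, near its clean-data baseline of ~6%. Slope variance
components estimated at zero are reported as such (their generating
values, 0.0012–0.28 on these predictor scales, are below what this design
can identify).

Other entry points: `bootstrap_power()` (detection power on 20%
sub-samples), `screen_demographics()`, `weekday_weekend_summary()`, and a
thin CLI over the same functions in `inst/scripts/sleeptrace.R` with
subcommands `simulate`, `measures`, `aggregate`, `fit`, `bootstrap`.

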