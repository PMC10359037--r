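Package: sleeptrace
Title: Behavioral Sleep Measures from Passive Smartphone Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives behavioral sleep measures from passively sensed
    human-smartphone interaction event streams: the daily inferred sleep
    period (longest run of 15-minute bins without interaction), the 30-day
    expected sleep period (longest inactive run of a k-means-binarized
    activity-fraction profile), the daily overlap percentage between the two
    (a sleep-timing regularity proxy), and nocturnal disruptions (active bins
    inside the expected sleep period). Provides survey scoring for the three
    DSM-5 Level 1 cross-cutting symptom domains (sleep disturbance,
    depression, anxiety), 14-day pre-survey aggregation with within/between-
    person decomposition, two-level linear mixed models of symptom severity
    on the behavioral measures with Cook's-distance influence filtering and
    Kolmogorov-Smirnov stability checks, ID-level bootstrap detection power,
    and a synthetic cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
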