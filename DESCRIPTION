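Package: reachnlme
Title: Learning-Fatigue Decomposition of Reach Training Movement Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of trial-by-trial movement times from intensive arm
    reach training. Movement times are extracted from fingertip
    trajectories (Butterworth smoothing, 5%-of-peak-speed onset/offset
    detection), decomposed with a nonlinear mixed-effects model into an
    exponential learning component, a linear activity-dependent fatigue
    component and per-target asymptotes, and summarised into per-subject
    learning and performance metrics. Population parameters are estimated
    by stochastic-approximation EM (SAEM) with per-subject empirical-Bayes
    modes. Includes the group-contrast and long-term-prediction statistics
    used in reach rehabilitation studies and a synthetic-cohort generator
    that reproduces the statistical structure of such studies for testing
    and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
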