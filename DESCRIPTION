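Package: rmstni
Title: Power and Sample Size for Non-Inferiority Trials with Treatment
    Switching Using Restricted Mean Survival Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation-based design of non-inferiority trials analysed by
    the difference in restricted mean survival times (RMST) under
    intention-to-treat when participants may switch treatment arms.
    Provides three non-inferiority margin constructions (preserved fraction
    of the control RMST, preserved fraction of the control-vs-placebo RMST
    difference, and conversion from a hazard-ratio margin),
    generalized-gamma event-time models calibrated from median survival,
    flexible accrual and dropout-censoring models calibrated from a target
    censoring probability, five switching-time distributions moment-matched
    to a mean-ratio and a correlation, a rank-preserving structural failure
    time counterfactual for switchers, an adjusted margin that restores
    type-I error control under switching, and Monte-Carlo power and
    sample-size calculation with monotone power-curve smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
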