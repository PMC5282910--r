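Package: cmrctsim
Title: Simulation and Instrumental-Variable Analysis of Trials Within Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying treatment refusal in individually randomised
    cohort multiple randomised controlled trials (cmRCT, "trials within
    cohorts") with time-to-event outcomes. Simulates trials from a Weibull
    proportional-hazards model with a shared individual frailty that drives
    both the event of interest and competing mortality, assigns
    intervention-arm refusal probabilities that may be correlated with
    underlying risk, and analyses each trial by intention-to-treat,
    per-protocol, and two instrumental-variable estimators (two-stage
    predictor substitution and two-stage residual inclusion). Includes
    replicate-level performance summaries (bias, power, empirical standard
    error), simulation-based sample-size calculation under recruitment with
    or without expected refusal, and scenario-grid experiment runners.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
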