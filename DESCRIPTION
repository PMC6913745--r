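Package: icubn
Title: Bayesian Network Analysis of Clinician Cardiac Function Estimates in
    Intensive Care
Version: 0.1.0
Authors@R:
    person("SICS", "Analytics", email = "sics.analytics@example.org",
           role = c("aut", "cre"))
Description: Discrete Bayesian-network analysis of how clinicians estimate
    cardiac function in acutely admitted intensive-care patients. Provides
    Max-Min Hill-Climbing structure learning with BDeu scoring and G2
    conditional-independence tests, bootstrap arc-confidence model averaging
    with thresholded consensus graphs, exact conditional-probability queries
    by variable elimination, sequential query trees, a calibrated synthetic
    cohort generator standing in for the (non-deposited) SICS-I data, and
    diagnostic-accuracy statistics (sensitivity, specificity, predictive
    values, likelihood ratios) with confidence intervals, including
    cross-validated network prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
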