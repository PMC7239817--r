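Package: hfnet
Title: Synthetic Cohorts and Circulating-Biomarker Network Analysis for
    Severe Heart Failure
Version: 0.1.0
Authors@R:
    person("hfnet", "developers", email = "hfnet@example.org",
           role = c("aut", "cre"))
Description: Tools to study how a multiplex panel of circulating plasma
    factors relates to myocardial function, physical capacity, daily
    physical activity and mortality in severe heart failure. Provides a
    calibrated synthetic case-control cohort generator with planted ground
    truth (correlated biomarker clusters, a latent-severity physiology
    block, accelerometer epoch traces and Weibull proportional-hazards
    survival); accelerometry wear-time and activity summarisation
    (Troiano non-wear rule, activity percentage, cpm skewness); univariate
    screening with Benjamini-Hochberg false-discovery control; two-class
    OPLS-DA with cross-validated Q2, VIP and bootstrap loading intervals;
    per-category principal-component summary scores and quadrant risk
    groups; mutual-information network inference with permutation tests,
    data-processing-inequality pruning and bootstrap correlation
    filtering; and from-scratch Cox proportional-hazards modelling with
    per-quartile hazard ratios and Kaplan-Meier estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
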