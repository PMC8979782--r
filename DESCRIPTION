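Package: wceclaims
Title: Weighted Cumulative Exposure Modelling of Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating how the dose, duration and recency of a
    dispensed medicine relate to the hazard of a hospitalization outcome,
    using the weighted cumulative exposure (WCE) approach. The package
    reconstructs daily exposure histories from dispensing claims under a
    supply-extension rule, applies a new-user eligibility cascade to build a
    cohort, estimates cubic-spline weight functions by stratified Cox
    partial likelihood with time-varying covariates, confirms estimates with
    an incidence-density nested case-control arm fitted by conditional
    logistic regression, and predicts hazard ratios for arbitrary exposure
    patterns. A claims simulator with a known true weight function supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
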