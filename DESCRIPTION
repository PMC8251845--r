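Package: matchvar
Title: Variability of Greedy Caliper Propensity-Score Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Monte-Carlo framework for quantifying how much the
    treatment-outcome odds ratio moves when greedy 1:1 caliper and
    nearest-neighbor-caliper propensity-score matching are repeated with
    different random orderings of the treated subjects in the same cohort.
    Simulates confounded binary-outcome cohorts from main-effects logistic
    treatment and outcome models with intercepts calibrated to target
    prevalences, estimates propensity scores by logistic regression, matches
    without replacement within a caliper expressed as a multiple of the
    propensity-score standard deviation, analyzes matched pairs by
    conditional logistic regression, checks covariate balance by
    standardized mean differences, and summarizes the across-seed
    distribution of the estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
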