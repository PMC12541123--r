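Package: hussurv
Title: Health Utility Adjusted Survival Composite Endpoints for Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and testing for health utility adjusted survival (HUS),
    a composite clinical-trial endpoint that integrates the Kaplan-Meier
    survival curve against the mean health utility of subjects still at risk,
    Q = int_0^T S(t)^lambda1 Ubar(t)^lambda2 dt. Provides the two-sample
    Q-difference statistic with bootstrap, permutation and jackknife decision
    rules; linear-interpolation imputation of sparse longitudinal utility
    scores; a piecewise-exponential analytic engine (X* transform, variance
    balance factors) for power analysis and sample-size calculation; trial
    simulators with calibrated uniform dropout censoring; and overall-survival
    comparator tests (one-sided log-rank superiority, hazard-ratio
    non-inferiority with margin).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
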