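Package: anchoritc
Title: Anchored Indirect Treatment Comparisons of Survival Outcomes
    Across Trial and Real-World Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anchored indirect treatment comparisons (Bucher
    method) of time-to-event outcomes between a randomized trial and a
    real-world cohort that share a common comparator regimen.  Includes a
    synthetic-cohort generator with informative treatment-discontinuation
    censoring and missing-at-random covariates, harmonized eligibility
    filtering with attrition accounting, multiple imputation by chained
    equations with Rubin's-rules pooling, propensity-score odds weighting
    of real-world treatment groups to a trial target population with
    standardized-difference balance diagnostics, weighted Cox
    proportional-hazards estimation with robust variance, and the anchored
    combination of direct hazard ratios with confidence-interval back-out
    utilities for checking published results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    nnet,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
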