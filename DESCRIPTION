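Package: prefiv
Title: Target-Trial Emulation with Prescriber-Preference Instrumental Variables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for emulating a three-arm comparative
    effectiveness trial of second-line oral antidiabetic drug classes
    (sulfonylureas, DPP-4 inhibitors, SGLT-2 inhibitors added to metformin)
    from linked routinely collected health data. Provides a synthetic
    linked-data generator with a fully known data-generating process,
    eligibility and measurement-window cohort construction, a regional
    prescribing-preference (tendency-to-prescribe) instrumental variable with
    relevance and balance diagnostics, two-stage residual inclusion estimation
    of average treatment effects for continuous and time-to-event outcomes
    (with gamma frailty), comparator estimators (two-stage least squares,
    multivariable regression, inverse probability of treatment weighting,
    doubly robust weighted regression), stratified multiple imputation by
    chained equations with predictive mean matching, and nested
    bootstrap-then-impute confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    glmnet,
    nnet,
    Rcpp,
    sandwich,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
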