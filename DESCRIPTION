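Package: hemoscreen
Title: Intraoperative Hypotension Burden Metrics and Exhaustive
    Combination Screening for Neurocognitive Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether intraoperative hemodynamic burden
    predicts neurocognitive impairment after on-pump cardiac surgery.
    Provides artifact filtering of invasive arterial-pressure time series,
    threshold-based hypotension burden metrics (absolute maximum decrease,
    time under threshold, area under threshold, time-weighted average),
    exhaustive predictor-subset screening with logistic regression
    (likelihood-ratio omnibus test, Cox & Snell and Nagelkerke pseudo-R2,
    Wald statistics and odds ratios) and random forest classification
    (stratified evaluation, cross-validation, impurity importance, partial
    dependence computed from first principles), a synthetic-cohort
    generator for testing the full pipeline without patient data, and an
    exact two-sample t-test power calculation for study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
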