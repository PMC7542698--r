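Package: pcmarkov
Title: Lifetime Cost-Effectiveness Markov Modelling of Localised
    Prostate Cancer Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A five-state annual-cycle Markov cohort model for the lifetime
    cost-utility analysis of three management strategies for clinically
    localised prostate cancer (active monitoring, radical prostatectomy,
    radical radiotherapy). Fits parametric (Weibull and exponential)
    proportional-hazards transition models to censored patient-level trial
    data, derives other-cause mortality from a cause-deleted national life
    table, estimates health-state utilities and state-by-strategy annual
    costs, and produces discounted lifetime costs, quality-adjusted life
    years, net monetary benefits, probabilistic sensitivity analysis
    percentile confidence intervals and cost-effectiveness acceptability
    curves, stratified by age and clinical risk subgroups. Includes a
    synthetic patient-level trial data generator with the same statistical
    structure, so the whole pipeline is testable end to end, including
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    flexsurv,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
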