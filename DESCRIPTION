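Package: gfrtools
Title: Glomerular Filtration Rate Estimation, Validation Metrics and
    Equation Development Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the metabolite-based GFR-NMR estimating equation
    (serum myo-inositol, valine, creatinine and cystatin C plus age and
    sex) together with the benchmark CKD-EPI and EKFC equations, and
    provides the machinery around such equations: validation metrics
    (median bias, IQR precision, MAE, RMSLE, 1-P15/20/30) with percentile
    bootstrap confidence intervals and paired significance tests, KDIGO
    CKD staging with net-reclassification-index analysis, exhaustive
    constrained enumeration of candidate model formulas with repeated
    cross-validation and configurable KPI filtering, piecewise sex- and
    cutoff-dependent model engineering, Vuong model comparison, and a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
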