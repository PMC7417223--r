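Package: mothmass
Title: Estimating Moth Body Mass and Sample Biomass from Forewing Length
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits allometric log-log mixed-effects models that predict the dry
    body mass of moths from their forewing length, with family-specific
    refinements for data-rich families and a species-level random intercept.
    Ships published reference parameters so biomass can be estimated for
    abundance-only light-trap datasets via field-guide forewing-length
    midpoints, and provides the full validation toolkit: Major Axis (model II)
    regression with one-tailed permutation tests and exact slope confidence
    intervals, train/test bootstrap resampling of the whole pipeline, and
    prediction-error-versus-sample-size curves. A synthetic moth-community
    generator with known allometric truth supports parameter-recovery and
    calibration experiments, and a command-line interface exposes the fitting,
    prediction, validation and simulation pipelines for CSV data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
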