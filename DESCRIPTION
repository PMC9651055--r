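Package: skyselect
Title: Scoring and Mixed-Model Analysis of Free-Selection "Sky as Nature"
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for image-based free-selection experiments in which
    participants click circular regions of outdoor scenes that they consider
    nature.  Provides a scene catalog built from LabelMe-style polygon
    annotations or indexed label masks, per-label surface quantification and
    derived covariates (percentage of sky, greenery and nature), the
    click-based EDB selection score and content-based semantic vector (CBSV),
    the data-quality rules applied to click counts and sky scores,
    nonparametric validation tests, and a stepwise ladder of crossed
    random-intercept mixed-effects models compared by AIC and likelihood-ratio
    tests with marginal and conditional R-squared.  A synthetic-data module
    simulates label-mask stimuli, participant click streams and subjective
    ratings under a known generating model so the whole pipeline can be
    exercised and validated without behavioural raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    lme4,
    png,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
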