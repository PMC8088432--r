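Package: amygconn
Title: Replication Analysis of an Amygdala-Connectivity Predictor of CBT
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating a frozen resting-state
    amygdala-connectivity biomarker of cognitive-behavioral therapy (CBT)
    response in social anxiety disorder. Implements Conn-style denoising of
    region-of-interest BOLD time series (motion and derivative regressors,
    tissue principal components, spike censoring, band-pass filtering),
    construction of the composite amygdala-connectivity term, application
    of a fixed-coefficient predictive model against a baseline-only compact
    model, prediction R-squared and model-based R-squared scoring with
    permutation inference, and closed-form power and confidence-interval
    calculations for correlation effect sizes. Includes a synthetic-cohort
    generator with planted effects so the full pipeline is testable
    end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
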