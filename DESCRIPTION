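Package: itascreen
Title: Iterative Thematic Analysis for High-Dimensional Survey Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements iterative thematic analysis (ITA) for rare binary
    outcomes measured in large-scale household surveys such as the
    Demographic and Health Surveys (DHS): survey-weighted L1-penalized
    logistic screening, L2-penalized refitting with cross-validated tuning,
    knee-point selection of the sorted coefficient curve (Kneedle),
    file-driven qualitative theme coding with inter-coder agreement, and
    iterative removal of the maximum-coefficient theme under explicit
    stopping rules. Ships a calibrated synthetic-data generator that
    emulates the DHS-like input (correlated themed variable blocks, bulk
    noise, sampling weights, calibrated outcome prevalence) so every stage
    of the pipeline is testable without access-restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
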