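Package: confmap
Title: Simulation and Analysis of Context-Dependent Confidence Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how private decision confidence is mapped
    onto public confidence reports in social perceptual decision making.
    Provides a signal-detection-theory simulator of perceptual choices and
    confidence, stimulus calibration to target accuracies, simulated
    partner agents with exactly controlled confidence-report distributions,
    factorial task designs with a confidence-based group-decision rule, an
    ordinal probit model of confidence reports with a counterfactual
    "private confidence" estimator, split-data representational
    dissimilarity analysis with the exemplar discriminability index (EDI),
    trial-locked ROI time-course and psychophysiological-interaction (PPI)
    regressions, and synthetic-data generators for behaviour, multivoxel
    patterns and BOLD-like time courses so that every analysis stage can be
    validated end to end.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
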