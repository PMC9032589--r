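Package: wristfunc
Title: Wrist Accelerometry Activity Recognition and Energy Expenditure in Older Adults
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for recognizing physical activity type,
    intensity and individual activities, and for estimating energy
    expenditure, from raw tri-axial wrist accelerometry in older adults
    stratified by physical performance. Extracts 49 time- and
    frequency-domain features from 60 s windows, trains gradient-boosted
    trees and L1-penalized linear models under subject-wise nested
    cross-validation, and evaluates robustness across low and high
    physical-performance groups with leave-one-group-out and
    leave-partial-group-out transfer experiments. Ships a synthetic cohort
    generator (activity signatures, SPPB scores, indirect calorimetry with
    a steady-state plateau) so the full analysis is runnable without
    laboratory data.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
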