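Package: sdcArea
Title: Small-Area Re-Identification Risk Assessment for Health Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding when a geographic area (such as a Canadian
    Forward Sortation Area) is too small to disclose in a health dataset.
    Computes equivalence classes and sample uniqueness on quasi-identifiers,
    estimates population uniqueness from a sample with the Zayatz estimator,
    enumerates quasi-identifier models and their MaxCombs values, fits
    logistic risk models predicting whether population uniqueness exceeds the
    5% or 20% thresholds (with down-sampling prior correction and King-Zeng
    rare-events corrections for unbalanced data), evaluates them by stratified
    10-fold cross-validation, and produces suppression reports. Includes a
    synthetic census-like microdata generator with exact ground-truth
    uniqueness so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
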