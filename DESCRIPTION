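Package: hyperbox
Title: Hyper-Box Enclosure Classification for Gene-Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mixed-integer-programming based hyper-box enclosure (HBE)
    classification of tumor types from gene-expression matrices. Provides
    min-max scaling and stratified cross-validation splits, filter-based gene
    ranking (information gain with MDL discretization, ReliefF,
    correlation-based feature selection), an integer-programming seed finder
    with a totally unimodular constraint set, exact construction of
    class-labeled hyper-boxes for problematic samples, deterministic
    intersection elimination, an F-distribution variance-ratio search for an
    optimal predictor gene set, evaluation harnesses (test set, repeated
    k-fold, leave-one-out), and synthetic data generators that emulate
    microarray study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
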