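Package: dcsynth
Title: Divide-and-Conquer Synthetic Tabular Data Generation for Clinical Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates synthetic single-table clinical data that preserves
    deterministic logical relationships between columns (for example,
    non-smoker implies zero pack-years). The divide-and-conquer strategy
    partitions the original data by outcome class and by perfectly
    associated attribute pairs found with the Cramer V statistic, fits a
    Gaussian-copula generator per subset, samples each subset at a
    configurable class balance, and recombines. Includes a
    rejection-sampling (conditional sampling) baseline, fidelity metrics
    (Kolmogorov-Smirnov, total variation distance, correlation and
    contingency similarity with shape/pair-trend/overall aggregation),
    logical-consistency checking, and a train-on-synthetic/test-on-real
    utility harness with pluggable classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    rpart,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
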