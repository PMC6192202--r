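Package: ccrand
Title: Covariate-Constrained Randomisation for Small Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for covariate-constrained randomisation in randomised
    controlled trials with few randomisation units, as is typical in
    cluster randomised designs. The full set of two-arm allocation
    schemes for a fixed roster of units is enumerated (or a random
    subset sampled), every scheme is scored by a weighted sum of
    per-variable imbalance contributions, a set of sufficiently
    balanced schemes is preselected, and the final scheme is drawn at
    random among them. Fifteen imbalance metrics are provided for
    binary, categorical, integer and continuous baseline variables
    (chi-squared and rank-test p-value based measures, Minkowski-type
    distances on category proportions, Hellinger distance, symmetrised
    Kullback-Leibler divergences, quartile differences and the area
    between empirical CDFs), together with a comparison-study module
    computing pairwise Spearman rank correlations, distinct-value
    counts and optimal-subset overlap between metrics, a synthetic
    test-data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
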