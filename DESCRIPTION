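Package: longnet
Title: Longitudinal Network Analysis of Paired Questionnaire Item Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and comparison of regularized partial-correlation
    networks over questionnaire items measured on the same subjects at two
    waves. Provides pairwise-complete Spearman correlation input with
    positive-definite repair, EBIC-tuned graphical lasso estimation (the
    coordinate-descent solver is implemented in compiled code), strength and
    bridge-strength centrality, within/between-questionnaire edge summaries,
    case-dropping bootstrap stability with the correlation-stability (CS)
    coefficient, a paired permutation network-comparison test, scale scoring
    with paired t-tests and Cohen's d, and a latent Gaussian copula simulator
    for paired binary/ordinal item panels with known sparse graphical truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
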