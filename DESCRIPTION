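Package: symptomnet
Title: Regularized Partial-Correlation Networks for Anxiety-Depression Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end symptom-network analysis for ordinal mental-health
    screening instruments (GAD-7 and CES-D-10): cohort screening with a
    staged exclusion cascade, Spearman association matrices, sparse Gaussian
    graphical model estimation by graphical lasso with EBIC-based
    regularization selection (including a cross-validated variant and gamma
    sensitivity analysis), expected-influence and bridge-expected-influence
    centrality, nonparametric and case-dropping bootstrap stability
    assessment with the correlation-stability coefficient, force-directed
    network layout and reporting, and a latent-copula ordinal data
    generator with planted partial-correlation structure for ground-truth
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    tools,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
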