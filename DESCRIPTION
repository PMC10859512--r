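Package: symptomnet
Title: Regularized Partial Correlation Networks for Depression and
    Anxiety Screening Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates Gaussian graphical models over ordinal screening-scale
    items (CESD-10 depression and GAD-7 anxiety) using Spearman correlations,
    graphical lasso regularization, and extended-BIC model selection.
    Computes expected influence and bridge expected influence centrality,
    and assesses network accuracy and stability with non-parametric and
    case-dropping bootstraps including the correlation-stability (CS)
    coefficient. Ships a latent-Gaussian (copula) generator for skewed
    ordinal survey data with survey-style missingness, so pipelines can be
    validated by parameter recovery without access to restricted survey
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
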