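Package: clpnet
Title: Cross-Lagged Panel Networks for Ordinal Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and stability analysis of directed cross-lagged panel
    networks (CLPN) from two-wave panel data of ordinal symptom items, as used
    to study temporal dynamics of psychological distress. Edges are
    standardized regression coefficients from node-wise LASSO regressions
    (cyclic coordinate descent with cross-validated penalty selection);
    node importance is quantified by in- and out-expected-influence.
    Includes nonparametric bootstrap accuracy and difference tests, case-drop
    bootstrap stability with the CS-coefficient, single-dataset predictive
    mean matching imputation under a missing-at-random assumption, GHQ-12
    scoring and descriptive psychometrics, and a synthetic panel generator
    (sparse latent VAR(1) process, ordinal discretization,
    covariate-dependent missingness) for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
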