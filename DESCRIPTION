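Package: deltscape
Title: Hierarchical Bayesian Occurrence Models for Fish DELT Anomalies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regional analyses of external fish anomalies (deformity,
    erosion, lesion, tumor, parasite; DELT) in multi-agency stream surveys.
    Harmonizes per-anomaly agency records to a binary DELT indicator, prepares
    upstream-watershed landscape predictors (multi-year aggregation,
    standardization, Spearman collinearity screening), and fits Bayesian
    hierarchical logistic occurrence models with crossed species, collection
    agency and ecoregion random effects and a regularized horseshoe prior for
    sparse landscape-predictor selection. Includes a built-in Hamiltonian Monte
    Carlo (NUTS) sampler, convergence diagnostics, posterior decision summaries
    (90% credible intervals, probability of direction, significance classes,
    group occurrence probabilities, response curves), and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
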