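Package: ascvdbn
Title: Discrete Bayesian Networks for Cardiovascular Risk-Factor Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models atherosclerotic cardiovascular disease (ASCVD) risk
    factors in cross-sectional cohorts with discrete Bayesian networks.
    Provides clinical discretization of anthropometric and lipid measurements,
    descriptive epidemiology (Fisher's exact tests, risk differences with
    Newcombe intervals, exact binomial prevalence), a literature-derived
    13-node network over demographic, metabolic and lipid variables,
    conditional-probability-table estimation with Dirichlet smoothing,
    score-based structure search by hill climbing on the BDeu score, exact
    posterior inference by variable elimination, d-separation queries,
    AIC/BIC model comparison, leave-one-out cross-validated diagnostic
    indices (ROC/AUC, sensitivity, specificity, predictive values,
    likelihood ratios), per-arc strength-of-influence summaries, and a
    calibrated synthetic-cohort generator for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
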