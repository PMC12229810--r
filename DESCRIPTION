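Package: sdmstack
Title: Expert-Informed Stacked-Generalization Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-tier stacked-generalization ensembles for presence-background
    species distribution modelling. Four tuned base learners (GLM with
    AIC-selected second-order polynomials, GAM with 3-knot thin-plate smooths,
    MaxEnt-style L1-penalized feature regression, and down-sampled random
    forest) feed a logistic-regression meta-learner, optionally together with
    a continuous distance-to-expert-range-polygon predictor. Includes
    occurrence thinning, calibration-area buffering, background sampling,
    collinearity screening, presence-background evaluation (continuous Boyce
    index, AUC, TSS, exact paired Wilcoxon signed-rank tests), 10% omission
    thresholding, spherical range-area summaries, and a virtual-species
    simulator with a latitudinal dispersal barrier for validating expert-map
    integration against a known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
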