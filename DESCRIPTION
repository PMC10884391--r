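Package: hepkin
Title: Dual-Input Compartment Modelling of Dynamic FDG PET in the Liver
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic analysis of short-protocol dynamic 18F-FDG PET of the
    liver with dual-input (hepatic artery + portal vein) compartment models.
    Implements forward simulation of the three-compartment (3C) model and a
    four-compartment (4C) model with an endoplasmic-reticulum FDG6P pool,
    weighted nonlinear least-squares parameter estimation with multistart
    Levenberg-Marquardt, AIC model comparison, cohort statistics with single-
    and multi-parameter ROC analysis, voxelwise parametric-map generation,
    and a synthetic-data generator emulating a 5-min dynamic plus 60-min
    static acquisition protocol.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    glmnet,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
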