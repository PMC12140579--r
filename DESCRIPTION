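Package: srcdcm
Title: Effective-Connectivity Phenotype Prediction for a Stimulus-Response
    Compatibility fMRI Network
Version: 0.1.0
Authors@R: person("srcdcm", "maintainers", email = "srcdcm@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting individual phenotypes
    (reaction time, age) from task-fMRI effective connectivity in a
    nine-node stimulus-response-compatibility (SRC) network.  Simulates
    SRC task paradigms and ROI BOLD cohorts from a bilinear dynamic
    causal model (DCM) with a balloon hemodynamic observation model,
    inverts per-subject DCMs by variational Laplace to obtain intrinsic
    (A-matrix) and task-modulated (B-matrix) connectivity posteriors,
    selects behavior-covarying connections with cross-validated
    parametric empirical Bayes (PEB) and Bayesian model reduction (BMR),
    and predicts subject scores with LASSO or ridge regression under
    k-fold or leave-one-out cross-validation, permutation nulls, and a
    CPM-style functional-connectivity comparison arm.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
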