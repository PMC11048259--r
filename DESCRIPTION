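Package: efastcnn
Title: Two-Stage CNN Optimization and Leave-One-Subject-Out Evaluation for
    eFAST Ultrasound Triage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic eFAST (extended Focused Assessment with Sonography for
    Trauma) ultrasound phantom generation and a complete convolutional
    neural network (CNN) model-development pipeline for binary injury
    classification at six scan sites (RUQ, BLD, PTX_B, PTX_M, HTX_B,
    HTX_M). Provides speckled B-mode and M-mode phantom rendering with
    per-subject random effects and a tunable injury effect size;
    preprocessing (cropping, bilinear resizing, M-mode rolling-window
    splitting, class-balanced sampling, image augmentation); a small CNN
    engine with softmax or softplus heads trained by RMSprop, ADAM, or
    SGDM with validation-patience early stopping; an exhaustive 54-run
    hyperparameter grid with score-aggregation parameter selection;
    Gaussian-process Bayesian optimization over the CNN architecture;
    leave-one-subject-out cross-validation with confusion-matrix metrics
    and AUROC; and Grad-CAM saliency maps for model auditing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
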