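Package: mammonode
Title: Preoperative Axillary Lymph Node Metastasis Prediction from Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale implementation of a three-step deep-learning workflow
    for predicting axillary lymph node metastasis (LNM) in early breast cancer
    from full-breast mammograms and preoperative clinical variables:
    self-supervised pretraining of a convolutional backbone on unlabeled image
    patches (Barlow Twins, BYOL, SwAV), multi-task supervised training of a
    neck module (residual blocks or a vision Transformer with shifted patch
    tokenization and locality self-attention) predicting five postoperative
    outcomes, and patient-level fusion of mammogram features with clinical
    predictors in a small MLP classifier. Includes a seeded synthetic phantom
    cohort generator, nested (double) cross-validation orchestration, a
    decision-analytic evaluation layer (ROC/PR AUC, operating points at fixed
    sensitivity, SLNB reduction rate, net benefit and decision curves,
    calibration, bootstrap and permutation inference), univariable effect-size
    statistics (Welch t, chi-square, Cohen's d, df-scaled Cramer's V), and
    model interpretation via permutation-sampling Shapley values and Grad-CAM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
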