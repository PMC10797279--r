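Package: dapehr
Title: Contrastive Pre-Training and Fine-Tuning for Post-Discharge
    Depression and Anxiety Risk Prediction from Heterogeneous EHRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a two-step deep-learning
    framework for predicting post-discharge depression and anxiety in
    type 2 diabetes patients from heterogeneous electronic health
    records. The first step pre-trains a multi-view encoder with a
    paired InfoNCE contrastive loss that aligns a fused patient-state
    representation with discharge-diagnosis and medication
    representations; the second fine-tunes the encoder for
    window-specific (30/180/365-day) risk prediction. The package also
    provides a seeded synthetic EHR generator with planted latent
    structure, cohort construction (outcome code sets, prior-event
    exclusion, record merging, 1:3 propensity-score matching),
    isolation-forest outlier screening, quantile discretization,
    k-fold evaluation with ROC-AUC/PR-AUC and decision curve analysis,
    and integrated-gradients interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    ranger,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
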