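Package: frailvoice
Title: Vocal-Biomarker Frailty Classification with Self-Supervised Speech Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for classifying frailty status
    (robust versus prefrail/frail by the K-FRAIL questionnaire) from voice
    recordings and demographics. Provides seeded synthetic cohort generation
    with class-dependent source-filter speech synthesis, 60-dimensional
    MFCC-based acoustic feature extraction with first- and second-order
    regression deltas, three modular classifiers (speech-only,
    demographics-only, combined) built on a transformer speech encoder with
    masked-frame self-supervised pretraining and frozen-backbone fine-tuning,
    and an evaluation layer with balanced stratified cross-validation,
    fold-level confidence intervals, paired AUC tests, prevalence-shifted
    sensitivity analysis and classical feature-based baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    yaml,
    withr,
    rpart,
    randomForest,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
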