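Package: vocload
Title: Vocal Biomarkers of Cognitive Load from Adaptive Digit Span Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for deriving a vocal biomarker of
    mental effort from the adaptive backwards digit span task. Provides a
    seeded state machine for adaptive task administration with multi-engine
    speech-recognition adjudication, a synthetic cohort generator whose
    acoustic feature vectors shift with relative cognitive load, frame-based
    paralinguistic feature extraction (low-level descriptors aggregated by
    statistical functionals), personalized load labeling with within-subject
    normalization, participant-wise data splitting, five reference classifier
    configurations, and ROC/AUC evaluation with span-restricted validation,
    permutation controls, and a diagnostic-accuracy sample-size utility.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
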