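Package: gradenav
Title: Reinforcement-Learning Slice Navigation for Patient-Level Tumor Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a slice-level convolutional grade classifier to a deep
    Q-network agent that navigates a 3D image stack to an attentional
    "decision slice" and emits a patient-level five-category grade group,
    mimicking how a radiologist scrolls a prostate MRI volume. Includes a
    synthetic volumetric phantom generator with graded lesion signatures, the
    full concordance-evaluation suite (accuracy, quadratic-weighted Cohen's
    kappa, per-grade precision/recall/F1 with bootstrap confidence intervals,
    upgrading/downgrading decomposition, contingency-table tests, grouped
    ROC/AUC), NIfTI input/output, and a command-line interface, so the whole
    framework is trainable and auditable on one CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
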