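Package: cogload
Title: Multimodal Cognitive-Load Feature Extraction and Discriminant Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discriminating intrinsic and extraneous cognitive load
    from multimodal psychophysiological recordings (gaze position, pupil
    diameter, heart-rate pulse and galvanic skin resistance sampled at
    150 Hz). Implements dispersion-based (I-DT) fixation and saccade
    detection, upper-tail winsorization of oculometric outliers, the
    ambient/focal attention K coefficient, the Low-High Index of Pupillary
    Activity (LHIPA) via a periodized discrete wavelet transform,
    task-evoked pupil dilation, heart-rate variability (SDNN of smoothed
    inter-beat intervals from pulse peaks), and tonic skin-resistance level;
    split-half reliability with Spearman-Brown correction over many random
    splits; a four-group linear discriminant model on standardized
    predictors with multiclass evaluation (confusion matrix, per-class
    balanced accuracy, precision/recall/F1, exact accuracy confidence
    interval, Cohen's kappa, per-task ROC/AUC); and a seeded synthetic-data
    generator emulating the study design so the entire pipeline is testable
    without access to the original recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
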