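Package: SegEnsembleQC
Title: Label-Wise Quality Control for Multi-Label 3D Segmentation Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the label-wise accuracy of multi-label 3D segmentations
    from the disagreement among an ensemble of auxiliary predictions, and flags
    structures whose segmentation is insufficiently accurate for downstream
    morphometric analysis. Implements a panel of seven agreement metrics
    (intersection-over-union and intersection-over-prediction of the auxiliary
    predictions, their Dice-transformed forms, the average and median Dice
    between auxiliaries and the final prediction, and the coefficient of
    variation of the label volumes), a correction-extent definition of
    segmentation goodness, metric ranking by coefficient of determination,
    threshold calibration via a sensitivity-weighted Youden index, and
    sensitivity/specificity evaluation of the resulting classifier. A synthetic
    phantom module simulates ensembles of degraded predictions so the full
    calibration and evaluation pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
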