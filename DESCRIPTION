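Package: lesionbench
Title: Enhancement and Evaluation Toolkit for Ischaemic Stroke Lesion
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Wraps any voxelwise probability-map-producing brain lesion
    segmenter with the pre-processing, data augmentation, error-map weighted
    sampling, threshold tuning, morphological post-processing and evaluation
    machinery used in multi-channel MR perfusion stroke studies. Provides
    NIfTI grid resampling to an isotropic working space and exact restoration
    to native space, intracranial mask construction and in-mask intensity
    normalisation, offline intensity-variance augmentation with leakage-safe
    manifests, PR- and ROC-based threshold selection (THT0/THT1), 3-D ball
    binary closing with validation-tuned iteration counts (FH), voxel overlap
    and distance metrics (Dice, Matthews correlation, Hausdorff distance),
    per-fold and per-lesion-category aggregation with Bland-Altman volume
    agreement, a 5-fold cross-validation orchestrator for pluggable
    segmenters, and a multi-channel lesion phantom generator for fully
    synthetic end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
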