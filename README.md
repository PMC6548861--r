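# lesionbench

Pre-processing, data augmentation, error-map weighted sampling, threshold
tuning, morphological post-processing and evaluation machinery for
voxelwise ischaemic stroke lesion segmentation in multi-channel MR
perfusion/diffusion data (ADC, MTT, rCBF, rCBV, TTP). Any model that turns
co-registered NIfTI channels into per-voxel foreground/background
probability maps can be wrapped, enhanced and scored by this toolkit — the
segmenter itself is pluggable and is not part of the package.

It is aimed at researchers benchmarking segmentation enhancements
(augmentation, sampling schemes, post-processing) around an existing
probability-map-producing model, with full 5-fold cross-validation,
leakage guards, and fully synthetic phantom cohorts so every stage is
testable without any dataset download.

## What it computes

Given ground truth *G* and a binarised prediction *P* with voxel counts
TP, TN, FP, FN, the evaluation module reports

- TPR = TP/(TP+FN), TNR = TN/(TN+FP), PPV = TP/(TP+FP),
  ACC = (TP+TN)/(TP+TN+FP+FN)
- DSC = 2·TP/(2·TP+FP+FN) (Dice similarity coefficient)
- MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
- HD(G, P) = max{ max_g min_p d(g,p), max_p min_g d(p,g) } in mm
  (Hausdorff distance over foreground voxel centres)

and aggregates them per fold, per post-processing step and per lesion
category (lacunar/subcortical, small cortical, big cortical/main artery),
with Bland–Altman volume agreement (mean difference ± 1.96 SD limits).

Post-processing of a probability map `p`:

- **Base** — binarise at 0.5 (argmax of the two classes);
- **THT0** — threshold maximising precision·recall on the pooled
  validation voxels (PR-curve point furthest from the bottom-left corner,
  maximising the achievable Dice);
- **THT1** — threshold maximising TPR − FPR (Bookmaker Informedness, the
  ROC point furthest from the bottom-right corner);
- **FH** — binary closing of the Base mask with a radius-3 ball, the
  iteration count tuned as the rounded mean of per-validation-subject
  optima.

All tuning uses a fold's validation subjects only; outputs are restored to
each subject's native grid (exact inversion of the recorded resampling
transform) before tuning and evaluation.

## A worked example

```r
library(lesionbench)

cohort <- simulate_cohort(20, phantom_spec(seed = 11), seed = 11)
seg    <- degraded_segmenter(degradation_spec(blur_fwhm = 2, noise_sd = 0.05,
                                              hole_rate = 0.3, fp_rate = 1,
                                              seed = 7))
report <- run_experiment(cohort, seg, experiment_config(k = 5, seed = 11))
print(report)
#> <experiment_report> 5 folds (0 failed), 80 records
#>  postproc_step metric  n   mean ci_low ci_high
#>           Base    TPR 20  0.683  0.591   0.775
#>           Base    PPV 20  0.845  0.742   0.948
#>           Base    DSC 20  0.735  0.637   0.833
#>           Base     HD 20 12.544  8.098  16.989
#>             FH    TPR 20  0.701  0.603   0.798
#>             FH    PPV 20  0.835  0.734   0.936
#>             FH    DSC 20  0.740  0.640   0.839
#>             FH     HD 20 12.575  8.146  17.005
#>           THT0    TPR 20  0.850  0.771   0.930
#>           THT0    PPV 20  0.805  0.708   0.902
#>           THT0    DSC 20  0.810  0.719   0.901
#>           THT0     HD 20 12.645  8.084  17.205
#>           THT1    TPR 20  0.973  0.943   1.003
#>           THT1    PPV 20  0.686  0.603   0.769
#>           THT1    DSC 20  0.788  0.709   0.868
#>           THT1     HD 20 12.913  8.321  17.505
```

Read: on this synthetic cohort (degraded ground-truth probability maps
with interior holes, blur and noise), hole-filling (FH) improves mean Dice
over the raw 0.5-threshold binarisation; the ROC-based threshold (THT1)
drives sensitivity to 0.97 at the cost of the lowest precision of all
steps — the classic lesion-volume inflation of informedness-optimal
thresholds; and the PR-based threshold (THT0) gives the best Dice here.
Per-category summaries (`aggregate_metrics(report$records,
by = c("postproc_step", "category"))`) show big cortical lesions scoring
far higher Dice than the small subtypes under identical degradation.

A command-line interface over the same functions ships in
`inst/cli/lesionbench` (subcommands `simulate`, `preprocess`, `augment`,
`tune-threshold`, `close`, `evaluate`, `run`).

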