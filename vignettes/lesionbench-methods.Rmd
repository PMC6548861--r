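---
title: "Methods: enhancing and scoring a stroke-lesion segmenter with lesionbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancing and scoring a stroke-lesion segmenter with lesionbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionbench)
```

## What the package does

Automatic delineation of ischaemic stroke lesions in multi-channel MR
perfusion/diffusion data (ADC, MTT, rCBF, rCBV, TTP maps) is hard: lesions
vary enormously in location, size, shape and internal intensity, and the
voxelwise classifiers used for the task emit probability maps whose raw
0.5-threshold binarisation is rarely the best achievable segmentation.
`lesionbench` packages the machinery that surrounds such a segmenter — it
does not contain the segmenter itself. Any callable that turns pre-processed
channels into per-voxel foreground/background probabilities can be plugged
into the cross-validation orchestrator, enhanced with the augmentation and
weighted-sampling utilities, post-processed with tuned thresholds and
morphological closing, and scored with the standard overlap and distance
metrics.

The pipeline stages, in order:

1. **Pre-processing** (`preprocess_subject`). Each channel is resampled to
   an isotropic working space (default 1 mm) coarsened by a global
   downsampling factor `dF` (default 0.7, so the working voxel is
   ~1.43 mm — the downsampling that lets whole multi-channel heads fit into
   the memory budget of a patch-based trainer). An intracranial mask is
   built by binarising the TTP channel (non-zero voxels, since
   skull-stripped background is exactly zero) and dilating it with a
   radius-1 ball to improve the boundary; the mask is computed at native
   resolution and then resampled. Each resampled channel is z-normalised to
   zero mean and unit variance *inside the mask* (the mask is an argument
   of the normalisation step), with voxels outside the mask set to zero.
2. **Augmentation** (`intensity_variance_clone`, `augment_dataset`,
   `reflect_x`, `intensity_jitter`). Offline intensity-variance cloning
   replaces every in-lesion voxel, per channel independently, with an
   i.i.d. draw from a Gaussian matching that channel's in-lesion mean and
   SD — perturbing the lesion's internal texture while preserving its
   overall contrast. Clones are created for training subjects only; the
   manifest machinery refuses to clone validation or test subjects, so 43
   training subjects with one clone each always yield an 86-entry training
   manifest with zero leakage. The two online augmentations — mirroring
   along the X axis with probability 0.5, and the global jitter
   I' = (I + s)·m with s ~ N(0, 0.05²) and m ~ N(1, 0.01²), one (s, m)
   pair per call — are provided as callable operations for any wrapped
   trainer.
3. **Error-map weighted sampling** (`error_map`,
   `weighted_sample_centers`, `uniform_fg_bg_centers`). Per subject and
   class, the squared error between the class indicator of the ground
   truth and the predicted probability is z-normalised into a sampling
   weight map; patch centres are then drawn proportionally to the weights
   so a fine-tuning pass concentrates on the regions a previous model got
   wrong. The default balanced sampler (foreground or background with
   probability 0.5, then uniform within the region) is also provided.
4. **Restoration** (`restore_to_native`). Every model output is mapped back
   to the subject's native grid by exactly inverting the recorded forward
   transform, before any post-processing, so all tuning and evaluation
   happen in the original dimensional space.
5. **Post-processing** (`tune_threshold_tht0`, `tune_threshold_tht1`,
   `apply_threshold`, `binary_close`, `tune_closing_iterations`). THT0
   selects the probability threshold maximising precision·recall on the
   pooled validation voxels (the PR-curve point furthest from the
   bottom-left corner, which maximises the achievable Dice); THT1 maximises
   TPR − FPR (Bookmaker Informedness, the ROC point furthest from the
   bottom-right corner). The two tunings are independent and never
   combined. FH ("filling holes") closes the binarised prediction with a
   radius-3 ball, the iteration count chosen as the rounded mean of the
   per-validation-subject optima.
6. **Evaluation** (`metrics_record`, `aggregate_metrics`,
   `bland_altman`). TPR, TNR, PPV, ACC, DSC = 2TP/(2TP+FP+FN),
   MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)) and the Hausdorff
   distance (mm) per subject; means with 95% CIs per post-processing step,
   lesion category (plus an "all" stratum) and fold; Bland–Altman volume
   agreement with mean ± 1.96 SD limits.

`run_experiment` wires the stages into a k-fold cross-validation (default
k = 5) around the pluggable segmenter, guaranteeing that tuned parameters
for a fold derive only from that fold's validation subjects and that
augmentation clones never cross the train/validation/test boundary.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `dF` | 0.7 | global downsampling factor of the working space (dimensionless) |
| `target_spacing` | 1 mm | isotropic working spacing before `dF` |
| `dilation_radius`, `dilation_iters` | 1, 1 | ball dilation of the TTP-derived mask (voxels) |
| `clones_number` | 1 | intensity-variance clones per training subject |
| `shift_sigma`, `multi_sigma` | 0.05, 0.01 | SDs of the jitter shift/scale |
| `se_radius` | 3 | closing ball radius (voxels) for FH |
| `max_iter` | 5 | largest closing iteration count swept during tuning |
| `val_fraction` | 0.2 | share of a fold's non-test subjects used for tuning |
| `k` | 5 | cross-validation folds |

The validation fraction is a genuinely open choice (a study need only keep
tuning off the test cases); 20% keeps at least three tuning subjects per
fold at cohort sizes in the dozens while leaving most data for training.

## The synthetic cohort

`make_phantom`/`simulate_cohort` generate the cohorts every stage is tested
on: an ellipsoidal "head" with zero background; channels as base tissue
intensity plus an additive lesion contrast, Gaussian acquisition noise
(SD 4 on tissue intensities of 50–100), and a smooth random in-lesion
intensity modulation (15% relative amplitude) emulating the intensity
inhomogeneity of real infarcts; and one lesion per subject from one of
three clinical subtypes — lacunar/subcortical (a small deep sphere, radius
2–3 voxels), small cortical (one or two small blobs near the surface), and
big cortical/main artery (a large irregular union of 6–10 spheres in the
cortical band). The default category mix follows the 10/7/26 subtype
composition of a 43-subject acute stroke cohort. Lesion shapes are unions
of overlapping random spheres: no generative model of infarct morphology
is claimed, simplicity and controllability are the goals.

`degrade_gt_to_probs` emulates an imperfect segmenter by corrupting the
ground truth: interior voxels zeroed with a configurable hole rate (the
defect FH repairs), false-positive blobs, Gaussian blur of the class
boundary, and additive probability noise, clipped to [0, 1] with the
background class as the complement.

What passing tests on phantoms does **not** show: performance on real
perfusion data. The phantoms have no perfusion physics, no
perfusion/diffusion mismatch, no inter-channel misregistration, no
anisotropic acquisition, and their lesion boundaries are sharp. They
validate the *machinery* — that tuning is optimal for its objective, that
closing repairs the defects it is designed for, that the metrics are
exact, and that the qualitative orderings (hole filling helps Dice, the
ROC threshold trades precision for sensitivity, large lesions score
higher) emerge for the constructed reasons.

## Numerical choices

* **Interpolation.** Intensities and probability maps move between grids
  with separable linear interpolation; probabilities are clipped back to
  [0, 1]. Masks use "majority" resampling — linear interpolation of the
  0/1 indicator thresholded at 0.5 — which preserves binarity while
  keeping round-trip volume error under 5% and round-trip Dice above 0.95
  for solid shapes of radius ≥ 5 voxels at factor 0.7; plain
  nearest-neighbour (also available) loses roughly twice as much overlap
  on the same shapes. The forward transform (target spacing, factor,
  original shape/affine) is recorded with every resampled image, and
  restoration is exact inversion of that record, never re-estimation.
* **SD conventions.** Population SD (divide by N) for z-normalisation and
  for the intensity-variance draws, matching the convention of the tensor
  libraries patch-based segmenters are built on; sample SD (N − 1) for
  Bland–Altman limits and confidence intervals.
* **Thresholding.** Binarisation is strict (`p > t`). Candidate thresholds
  are the distinct probability values plus zero, which realise every
  binarisation reachable with t ∈ [0, 1]; ties on the tuning objective go
  to the highest threshold (conservative lesion volume). An uninformative
  map (no cut with TPR − FPR > 0) makes THT1 fall back to 0.5 with a
  warning.
* **Morphology.** A voxel belongs to the ball element iff its Euclidean
  offset length is at most the radius. Closing runs on a halo-padded grid
  covering the operation's full reach and is cropped afterwards, which
  makes extensivity and idempotence exact up to the image border; plain
  dilation/erosion treat outside-the-grid as background.
* **Closing tuning.** Per-subject optima over iterations 1..`max_iter`
  (ties to the smaller count), averaged as reals and rounded half-up; a
  warning is raised when closing never improves any validation subject.
* **Zero-denominator conventions.** TPR/TNR/PPV are 0 when undefined;
  DSC is 1 when both masks are empty and 0 on any other 0/0 ; MCC is 0
  when any marginal is zero. The Hausdorff distance is 0 when both masks
  are empty and undefined (NA, excluded from averages with the exclusion
  counted) when exactly one is — possible for small lesions with empty
  predictions.
* **Hausdorff computation.** Each directed distance is computed between
  the source-minus-target set and the 6-connectivity boundary of the
  target, which is provably identical to the full pairwise max–min for
  voxel-centre point sets and far cheaper; distances are in mm via the
  grid spacing.
* **Error-map sampling.** Z-scored weights can be negative; in-region
  weights are shifted so the minimum maps to a floor of 10⁻⁶ of the
  shifted maximum. Nonnegative raw weights are used as-is. Flat weights
  fall back to uniform sampling with a warning. Error maps are normalised
  over the whole grid (not brain-masked); sampling is what gets
  restricted to the valid region.
* **Determinism.** Every stochastic operation takes a seed; cohort
  generation, cloning and fold construction derive independent named
  sub-streams from one master seed, so adding subjects never perturbs
  existing draws.

## Design decisions

* **Restore before post-processing.** All segmenter outputs (probability
  maps included) are restored to native space first; threshold tuning,
  binarisation and closing then operate in the subjects' original
  dimensional space, where results are interpreted and volumes measured.
* **Static error maps.** The weighted-sampling maps are computed once from
  a previous model's predictions; per-epoch adaptive re-weighting is a
  known dynamic variant and out of scope.
* **Fold stratification** by lesion category is available but off by
  default; with heterogeneous cohorts the fold composition visibly moves
  the results, and the default mirrors plain shuffled folds.
* **Bundled segmenters.** `oracle_segmenter` (probabilities equal the
  working-space ground truth) validates the plumbing; `degraded_segmenter`
  (corrupted ground truth) exercises post-processing with known defects —
  both are test doubles that read the ground truth by construction.
  `reference_segmenter` (smoothed, sign-adjusted channel combination fed
  through a logistic) is an honest non-learning baseline. None is a CNN,
  and no claim about CNN-level performance follows from them.

## Problem sizes used in the shipped tests

The test-suite phantoms are 48³ voxels at 1 mm (working grid ~34³ at
1.43 mm after the 0.7-factor resampling), 20 subjects per cohort, 5 folds;
metric/threshold/morphology guarantees are checked against brute-force
oracles at 10⁴ replicates on small grids. These sizes were chosen so a
full run completes in minutes on one CPU while every guarantee is still
exercised at the stated statistical strength.

## Known limitations

* The package wraps, but does not provide, a trainable segmenter; no
  CNN-scale performance figures can be produced from the bundled
  components.
* Phantom realism is deliberately limited (see above); absolute metric
  values on phantoms say nothing about absolute performance on clinical
  data.
* Inputs are assumed skull-stripped and co-registered per subject; no
  bias-field correction, histogram matching or DICOM ingestion is
  provided.
* The Hausdorff distance is the maximum (not 95th-percentile) variant and
  is sensitive to single outlier voxels.

## A worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(8, phantom_spec(seed = 1), seed = 1)
seg <- degraded_segmenter(degradation_spec(hole_rate = 0.3, seed = 2))
report <- run_experiment(cohort, seg, experiment_config(k = 4, seed = 1))
print(report)
summary(report)          # means and 95% CIs per post-processing step
bland_altman(report$records)
```
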