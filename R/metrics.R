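#' Voxelwise confusion counts
#'
#' Counts true/false positives/negatives between a ground-truth and a
#' predicted mask, optionally restricted to an evaluation region. The four
#' counts always sum to the number of voxels in the region.
#'
#' @param gt ground-truth [binary_mask()].
#' @param pred predicted [binary_mask()] on the same grid.
#' @param region optional [binary_mask()] restricting the evaluation
#'   (default: whole grid).
#' @return Named numeric vector \code{c(TP, TN, FP, FN)}.
#' @export
confusion_counts <- function(gt, pred, region = NULL) {
  stop_if_grid_mismatch(gt, pred, "ground truth and prediction")
  g <- gt$voxels > 0
  p <- pred$voxels > 0
  if (!is.null(region)) {
    stop_if_grid_mismatch(gt, region, "ground truth and region")
    keep <- region$voxels > 0
    g <- g[keep]; p <- p[keep]
  }
  c(TP = sum(g & p), TN = sum(!g & !p), FP = sum(!g & p), FN = sum(g & !p))
}

#' Scalar overlap metrics from confusion counts
#'
#' Computes TPR (sensitivity/recall), TNR (specificity), PPV (precision),
#' ACC, DSC (Dice similarity coefficient, the harmonic mean of PPV and TPR,
#' equal to \eqn{2TP / (2TP + FP + FN)}) and MCC (Matthews correlation
#' coefficient, a balanced quality measure in [-1, 1] robust to class
#' imbalance).
#'
#' Zero-denominator conventions: TPR, TNR and PPV are 0 when their
#' denominator is 0; DSC is 1 when both masks are empty (and 0 on any other
#' 0/0); MCC is 0 whenever any marginal is zero.
#'
#' @param counts named vector as returned by [confusion_counts()].
#' @return Named numeric vector \code{c(TPR, TNR, PPV, ACC, DSC, MCC)}.
#' @export
scalar_metrics <- function(counts) {
  tp <- as.double(counts[["TP"]]); tn <- as.double(counts[["TN"]])
  fp <- as.double(counts[["FP"]]); fn <- as.double(counts[["FN"]])
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be nonnegative", call. = FALSE)
  ratio0 <- function(num, den) if (den > 0) num / den else 0
  tpr <- ratio0(tp, tp + fn)
  tnr <- ratio0(tn, tn + fp)
  ppv <- ratio0(tp, tp + fp)
  acc <- ratio0(tp + tn, tp + tn + fp + fn)
  dsc <- if (tp + fp + fn == 0) 1 else ratio0(2 * tp, 2 * tp + fp + fn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else {
    den <- sqrt(prod(marg))
    if (is.finite(den)) (tp * tn - fp * fn) / den
    else (tp * tn - fp * fn) / exp(0.5 * sum(log(marg)))  # overflow guard
  }
  c(TPR = tpr, TNR = tnr, PPV = ppv, ACC = acc, DSC = dsc, MCC = mcc)
}

#' Dice similarity coefficient of two masks
#'
#' Set-theoretically \eqn{2 |A \cap B| / (|A| + |B|)}; 1 when both masks
#' are empty.
#'
#' @param a,b [binary_mask()]s on one grid, or 0/1 arrays of one shape.
#' @return DSC in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  va <- if (inherits(a, "binary_mask")) a$voxels else a
  vb <- if (inherits(b, "binary_mask")) b$voxels else b
  inter <- sum(va > 0 & vb > 0)
  denom <- sum(va > 0) + sum(vb > 0)
  if (denom == 0) 1 else 2 * inter / denom
}

# 6-connectivity boundary: foreground voxels with at least one face
# neighbour outside the mask (or on the grid edge).
boundary6 <- function(arr) {
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  eroded <- morph_pass(arr, off, "erode")
  arr > 0 & !(eroded > 0 & arr > 0)
}

directed_hausdorff_mm <- function(coords_a, coords_b) {
  if (nrow(coords_a) == 0) return(0)
  chunk <- 2000L
  worst <- 0
  for (start in seq(1L, nrow(coords_a), by = chunk)) {
    ids <- start:min(start + chunk - 1L, nrow(coords_a))
    # squared distances block: |a|^2 + |b|^2 - 2 a.b
    a <- coords_a[ids, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(coords_b^2), "+") -
      2 * a %*% t(coords_b)
    row_min <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    worst <- max(worst, sqrt(max(0, max(row_min))))
  }
  worst
}

#' Hausdorff distance between two masks, in millimetres
#'
#' The maximum of the two directed max-min Euclidean distances between the
#' foreground voxel-centre point sets, with voxel indices scaled by the
#' grid spacing so the result is in mm. By convention the distance is 0
#' when both masks are empty; when exactly one is empty the distance is
#' undefined and \code{NA} is returned (callers exclude such subjects from
#' averages, reporting the excluded count).
#'
#' Internally each directed distance is computed between the source set
#' minus the target and the target's 6-connectivity boundary, which is
#' exactly equivalent to the full pairwise computation for voxel-centre
#' point sets and far cheaper.
#'
#' @param gt,pred [binary_mask()]s on one grid.
#' @return Hausdorff distance in mm (\code{NA} if exactly one mask is
#'   empty).
#' @export
hausdorff_distance <- function(gt, pred) {
  stop_if_grid_mismatch(gt, pred, "masks")
  a <- gt$voxels > 0
  b <- pred$voxels > 0
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(NA_real_)
  spacing <- gt$spacing
  coords_mm <- function(keep) {
    ind <- arrayInd(which(keep), dim(gt$voxels))
    sweep(ind - 1L, 2, spacing, "*")
  }
  d_ab <- directed_hausdorff_mm(coords_mm(a & !b), coords_mm(boundary6(b * 1)))
  d_ba <- directed_hausdorff_mm(coords_mm(b & !a), coords_mm(boundary6(a * 1)))
  max(d_ab, d_ba)
}

#' Landis-Koch strength-of-agreement band for a Dice score
#'
#' Maps a DSC value to the conventional agreement labels: below 0 "Poor",
#' up to 0.20 "Slight", up to 0.40 "Fair", up to 0.60 "Moderate", up to
#' 0.80 "Substantial", above "Almost perfect".
#'
#' @param dsc numeric vector of Dice scores.
#' @return Character vector of agreement labels.
#' @export
landis_koch <- function(dsc) {
  labels <- c("Poor", "Slight", "Fair", "Moderate", "Substantial",
              "Almost perfect")
  as.character(cut(dsc, breaks = c(-Inf, 0, 0.20, 0.40, 0.60, 0.80, Inf),
                   labels = labels, right = TRUE, include.lowest = FALSE))
}

#' Full per-subject metrics record
#'
#' Evaluates one prediction against its ground truth: confusion counts,
#' the six scalar metrics, Hausdorff distance (mm) and lesion volumes
#' (mm^3), tagged with the subject's lesion category, fold and
#' post-processing step — one row of the experiment report.
#'
#' @param gt,pred [binary_mask()]s on one (native-space) grid.
#' @param region optional evaluation-region mask.
#' @param category lesion category label (\code{"lacunar/subcortical"},
#'   \code{"small cortical"}, \code{"big cortical/main artery"}, ...).
#' @param fold_id,postproc_step provenance labels.
#' @return One-row data frame.
#' @export
metrics_record <- function(gt, pred, region = NULL, category = NA,
                           fold_id = NA, postproc_step = NA) {
  counts <- confusion_counts(gt, pred, region)
  m <- scalar_metrics(counts)
  data.frame(subject_id = gt$subject_id,
             TP = counts[["TP"]], TN = counts[["TN"]],
             FP = counts[["FP"]], FN = counts[["FN"]],
             TPR = m[["TPR"]], TNR = m[["TNR"]], PPV = m[["PPV"]],
             ACC = m[["ACC"]], DSC = m[["DSC"]], MCC = m[["MCC"]],
             HD = hausdorff_distance(gt, pred),
             gt_volume = mask_volume_mm3(gt),
             pred_volume = mask_volume_mm3(pred),
             category = category, fold_id = fold_id,
             postproc_step = postproc_step,
             stringsAsFactors = FALSE)
}
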