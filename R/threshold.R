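#' Precision-recall and ROC curves over pooled voxels
#'
#' Computes the curve over every achievable strict-inequality binarisation
#' \code{prediction = (p > t)} of the pooled foreground probabilities.
#' Candidate thresholds are the distinct probability values plus 0, which
#' together realise every distinct binarisation reachable with t in [0, 1].
#'
#' @param labels 0/1 vector of pooled ground-truth voxels.
#' @param probs numeric vector of pooled foreground probabilities.
#' @return Data frame with one row per candidate threshold: \code{threshold},
#'   counts \code{tp/fp/fn/tn}, \code{precision}, \code{recall} (= TPR) and
#'   \code{fpr}.
#' @keywords internal
threshold_curve <- function(labels, probs) {
  stopifnot(length(labels) == length(probs))
  pos <- sum(labels)
  neg <- length(labels) - pos
  u <- sort(unique(c(probs, 0)), decreasing = TRUE)
  ord <- order(probs, decreasing = TRUE)
  p_sorted <- probs[ord]
  l_sorted <- labels[ord]
  cum_tp <- cumsum(l_sorted)
  cum_n <- seq_along(l_sorted)
  # number of voxels with p > t for each candidate t
  n_above <- length(p_sorted) - findInterval(u, sort(p_sorted))
  tp <- ifelse(n_above == 0, 0, cum_tp[pmax(n_above, 1)])
  fp <- n_above - tp
  fn <- pos - tp
  tn <- neg - fp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- if (pos > 0) tp / pos else rep(0, length(tp))
  fpr <- if (neg > 0) fp / neg else rep(0, length(fp))
  data.frame(threshold = u, tp = tp, fp = fp, fn = fn, tn = tn,
             precision = precision, recall = recall, fpr = fpr)
}

concat_voxels <- function(gts, probs, max_negatives = Inf, seed = 1) {
  if (inherits(gts, "binary_mask")) gts <- list(gts)
  if (inherits(probs, "probability_map")) probs <- list(probs)
  if (length(gts) != length(probs)) {
    stop("ground-truth and probability-map lists must align per subject",
         call. = FALSE)
  }
  labels <- numeric(0); p <- numeric(0)
  for (i in seq_along(gts)) {
    stop_if_grid_mismatch(gts[[i]], probs[[i]], "ground truth and probabilities")
    labels <- c(labels, as.vector(gts[[i]]$voxels))
    p <- c(p, as.vector(probs[[i]]$fg))
  }
  if (sum(labels) == 0 || sum(labels) == length(labels)) {
    stop("pooled ground truth must contain both classes", call. = FALSE)
  }
  neg <- which(labels == 0)
  if (is.finite(max_negatives) && length(neg) > max_negatives) {
    # stratified subsample: keep every positive, thin the negatives
    keep <- sort(c(which(labels == 1),
                   with_seed(seed, sample(neg, max_negatives))))
    labels <- labels[keep]; p <- p[keep]
  }
  list(labels = labels, probs = p)
}

tune_threshold <- function(gts, probs, method, fold_id,
                           max_negatives = Inf, seed = 1) {
  v <- concat_voxels(gts, probs, max_negatives = max_negatives, seed = seed)
  curve <- threshold_curve(v$labels, v$probs)
  if (method == "THT0") {
    objective <- curve$precision * curve$recall
    points <- data.frame(x = curve$recall, y = curve$precision,
                         threshold = curve$threshold)
  } else {
    objective <- curve$recall - curve$fpr
    points <- data.frame(x = curve$fpr, y = curve$recall,
                         threshold = curve$threshold)
  }
  best <- max(objective)
  if (method == "THT1" && best <= 1e-12) {
    warning("uninformative probability map: TPR - FPR <= 0 at every threshold; falling back to 0.5",
            call. = FALSE)
    threshold <- 0.5
  } else {
    # ties broken towards the highest threshold (fewest positives)
    cand <- which(objective >= best - 1e-12)
    threshold <- max(curve$threshold[cand])
  }
  structure(list(method = method, threshold = threshold,
                 objective = best, curve_points = points, fold_id = fold_id),
            class = "threshold_tuning")
}

#' THT0: PR-curve threshold selection
#'
#' Pools the ground truth and foreground probabilities of all supplied
#' subjects, computes the precision-recall curve and returns the threshold
#' maximising \code{precision * recall} — the point furthest from the
#' bottom-left corner of the PR plane, and the cut that maximises the Dice
#' score achievable by thresholding. Ties go to the highest threshold
#' (conservative lesion volume). Intended to be tuned on a fold's
#' validation subjects and applied to its test subjects.
#'
#' @param gts list of ground-truth [binary_mask()]s (or a single mask).
#' @param probs list of [probability_map()]s aligned with \code{gts}.
#' @param fold_id optional fold identifier carried in the result.
#' @param max_negatives optional cap on pooled negative voxels (all
#'   positives are always kept; negatives beyond the cap are subsampled
#'   with \code{seed}) for memory-constrained curve computation; off
#'   (\code{Inf}) by default.
#' @param seed RNG seed for the negative subsample.
#' @return An object of class \code{threshold_tuning} with fields
#'   \code{method}, \code{threshold}, \code{objective}, \code{curve_points}
#'   (x, y, threshold triples) and \code{fold_id}.
#' @export
tune_threshold_tht0 <- function(gts, probs, fold_id = NA,
                                max_negatives = Inf, seed = 1) {
  tune_threshold(gts, probs, "THT0", fold_id, max_negatives, seed)
}

#' THT1: ROC-curve threshold selection
#'
#' As [tune_threshold_tht0()] but on the ROC curve, maximising
#' \code{TPR - FPR} (the Bookmaker Informedness) — the point furthest from
#' the bottom-right corner. Falls back to 0.5 with a warning when the map
#' is uninformative (no threshold attains a positive objective).
#'
#' @inheritParams tune_threshold_tht0
#' @return An object of class \code{threshold_tuning}.
#' @export
tune_threshold_tht1 <- function(gts, probs, fold_id = NA,
                                max_negatives = Inf, seed = 1) {
  tune_threshold(gts, probs, "THT1", fold_id, max_negatives, seed)
}

#' @param x a \code{threshold_tuning} object.
#' @param ... passed to [graphics::plot()].
#' @rdname tune_threshold_tht0
#' @export
plot.threshold_tuning <- function(x, ...) {
  is_pr <- x$method == "THT0"
  pts <- x$curve_points[order(x$curve_points$x), ]
  graphics::plot(pts$x, pts$y, type = "l",
                 xlab = if (is_pr) "recall (TPR)" else "FPR",
                 ylab = if (is_pr) "precision (PPV)" else "TPR",
                 xlim = c(0, 1), ylim = c(0, 1),
                 main = sprintf("%s curve (tuned threshold %.3f)",
                                if (is_pr) "Precision-recall" else "ROC",
                                x$threshold), ...)
  at <- which.min(abs(x$curve_points$threshold - x$threshold))
  graphics::points(x$curve_points$x[at], x$curve_points$y[at], pch = 19)
  invisible(x)
}

#' @export
print.threshold_tuning <- function(x, ...) {
  cat(sprintf("<threshold_tuning> %s: threshold %.4f (objective %.4f)%s\n",
              x$method, x$threshold, x$objective,
              if (is.na(x$fold_id)) "" else sprintf(", fold %s", x$fold_id)))
  invisible(x)
}

#' Binarise a probability map at a threshold
#'
#' A voxel is foreground iff its foreground probability is strictly greater
#' than \code{t}. With \code{t = 0.5} this equals the argmax ("Base")
#' prediction of a two-class map (up to exact-0.5 ties, which go to
#' background).
#'
#' @param probs a [probability_map()].
#' @param t threshold in [0, 1].
#' @return A [binary_mask()] on the same grid.
#' @export
apply_threshold <- function(probs, t = 0.5) {
  if (t < 0 || t > 1) stop("threshold must be in [0, 1]", call. = FALSE)
  binary_mask(probs$fg > t, affine = probs$affine,
              subject_id = probs$subject_id, channel = "prediction",
              transform = probs$transform)
}

#' Tune the closing iteration count on validation subjects (FH)
#'
#' For every validation subject, sweeps closing iteration counts 1..
#' \code{max_iter} with the given ball radius and records the count that
#' maximises that subject's Dice score against its ground truth (ties to
#' the smaller count). The final count is the mean of the per-subject
#' optima, rounded half-up. A warning is issued when closing never improves
#' on the unclosed prediction for any subject.
#'
#' @param gts_val list of validation ground-truth [binary_mask()]s.
#' @param masks_val list of binarised validation predictions, aligned.
#' @param se_radius structuring-element ball radius in voxels; default 3.
#' @param max_iter largest iteration count swept; default 5.
#' @param fold_id optional fold identifier.
#' @return A list of class \code{closing_config} with \code{se_radius},
#'   \code{iterations}, \code{per_subject_optima} and \code{fold_id}.
#' @export
tune_closing_iterations <- function(gts_val, masks_val, se_radius = 3,
                                    max_iter = 5, fold_id = NA) {
  if (inherits(gts_val, "binary_mask")) gts_val <- list(gts_val)
  if (inherits(masks_val, "binary_mask")) masks_val <- list(masks_val)
  if (length(gts_val) == 0) {
    stop("validation set is empty", call. = FALSE)
  }
  if (length(gts_val) != length(masks_val)) {
    stop("validation ground truths and predictions must align", call. = FALSE)
  }
  optima <- integer(length(gts_val))
  improved <- logical(length(gts_val))
  for (i in seq_along(gts_val)) {
    base_dsc <- dice_coefficient(gts_val[[i]], masks_val[[i]])
    best_dsc <- -Inf
    best_it <- 1L
    for (it in seq_len(max_iter)) {
      closed <- binary_close(masks_val[[i]], radius = se_radius,
                             iterations = it)
      d <- dice_coefficient(gts_val[[i]], closed)
      if (d > best_dsc + 1e-12) {
        best_dsc <- d
        best_it <- it
      }
    }
    optima[i] <- best_it
    improved[i] <- best_dsc > base_dsc + 1e-12
  }
  if (!any(improved)) {
    warning("closing does not improve DSC on any validation subject; hole filling may not be beneficial",
            call. = FALSE)
  }
  iterations <- as.integer(floor(mean(optima) + 0.5))  # round half-up
  structure(list(se_shape = "ball", se_radius = se_radius,
                 iterations = iterations, per_subject_optima = optima,
                 fold_id = fold_id),
            class = "closing_config")
}

#' @export
print.closing_config <- function(x, ...) {
  cat(sprintf("<closing_config> ball radius %g, %d iteration(s) (per-subject optima: %s)\n",
              x$se_radius, x$iterations,
              paste(x$per_subject_optima, collapse = ", ")))
  invisible(x)
}
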