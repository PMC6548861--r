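# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops, direct formulas) so they cannot share a
# defect with the vectorised implementations they check.

random_mask <- function(dims, p = 0.3) {
  binary_mask(array(stats::runif(prod(dims)) < p, dims))
}

solid_sphere_mask <- function(n, radius, spacing = c(1, 1, 1)) {
  c0 <- rep((n + 1) / 2, 3)
  i <- seq_len(n)
  d <- sqrt(outer(outer((i - c0[1])^2, (i - c0[2])^2, "+"), (i - c0[3])^2, "+"))
  binary_mask(d <= radius, spacing = spacing)
}

# Direct contingency-table metric oracle (independent of scalar_metrics).
oracle_metrics <- function(gt_vec, pred_vec) {
  tp <- sum(gt_vec == 1 & pred_vec == 1)
  tn <- sum(gt_vec == 0 & pred_vec == 0)
  fp <- sum(gt_vec == 0 & pred_vec == 1)
  fn <- sum(gt_vec == 1 & pred_vec == 0)
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(TP = tp, TN = tn, FP = fp, FN = fn,
    TPR = sdiv(tp, tp + fn), TNR = sdiv(tn, tn + fp),
    PPV = sdiv(tp, tp + fp), ACC = sdiv(tp + tn, tp + tn + fp + fn),
    DSC = if (tp + fp + fn == 0) 1 else sdiv(2 * tp, 2 * tp + fp + fn),
    MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

# Exhaustive pairwise max-min Hausdorff oracle over voxel centres (mm).
oracle_hausdorff <- function(gt, pred) {
  a <- arrayInd(which(gt$voxels > 0), dim(gt$voxels))
  b <- arrayInd(which(pred$voxels > 0), dim(pred$voxels))
  if (nrow(a) == 0 && nrow(b) == 0) return(0)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  am <- sweep(a - 1L, 2, gt$spacing, "*")
  bm <- sweep(b - 1L, 2, gt$spacing, "*")
  directed <- function(x, y) {
    worst <- 0
    for (i in seq_len(nrow(x))) {
      best <- Inf
      for (j in seq_len(nrow(y))) {
        best <- min(best, sqrt(sum((x[i, ] - y[j, ])^2)))
      }
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(am, bm), directed(bm, am))
}

# Exhaustive neighbourhood-scan morphology oracle.
oracle_morph <- function(arr, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(arr)
  out <- array(0, d)
  r <- ceiling(radius)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    hit <- if (op == "dilate") 0 else 1
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      if (sqrt(di^2 + dj^2 + dk^2) > radius + 1e-9) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      v <- if (ii < 1 || jj < 1 || kk < 1 ||
               ii > d[1] || jj > d[2] || kk > d[3]) 0 else arr[ii, jj, kk]
      if (op == "dilate" && v == 1) { hit <- 1; break }
      if (op == "erode" && v == 0) { hit <- 0; break }
    }
    out[i, j, k] <- hit
  }
  out
}

# Dense grid-search threshold oracle: best objective over t = 0, 1e-3, ..., 1
# using the same strict-inequality binarisation.
oracle_best_objective <- function(labels, probs, objective = c("pr", "roc")) {
  objective <- match.arg(objective)
  pos <- sum(labels); neg <- length(labels) - pos
  best <- -Inf
  for (t in seq(0, 1, by = 1e-3)) {
    pred <- probs > t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    val <- if (objective == "pr") {
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (pos > 0) tp / pos else 0
      prec * rec
    } else {
      (if (pos > 0) tp / pos else 0) - (if (neg > 0) fp / neg else 0)
    }
    best <- max(best, val)
  }
  best
}

eval_objective <- function(labels, probs, t, objective = c("pr", "roc")) {
  objective <- match.arg(objective)
  pos <- sum(labels); neg <- length(labels) - pos
  pred <- probs > t
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  if (objective == "pr") {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (pos > 0) tp / pos else 0
    prec * rec
  } else {
    (if (pos > 0) tp / pos else 0) - (if (neg > 0) fp / neg else 0)
  }
}

# Small multi-channel test subject on its native grid.
tiny_subject <- function(id = "s1", n = 16, seed = 42, lesion_radius = 3) {
  set.seed(seed)
  c0 <- rep((n + 1) / 2, 3)
  i <- seq_len(n)
  dist <- sqrt(outer(outer((i - c0[1])^2, (i - c0[2])^2, "+"),
                     (i - c0[3])^2, "+"))
  head <- dist <= n * 0.45
  lesion <- dist <= lesion_radius
  mk_channel <- function(ch, base, contrast) {
    arr <- array(0, c(n, n, n))
    arr[head] <- base + stats::rnorm(sum(head), 0, 2)
    arr[lesion] <- arr[lesion] + contrast
    if (ch == "TTP") arr[head] <- pmax(arr[head], 1)
    subject_volume(arr, spacing = c(1, 1, 1), subject_id = id, channel = ch)
  }
  list(subject_id = id,
       channels = list(ADC = mk_channel("ADC", 100, -30),
                       MTT = mk_channel("MTT", 80, 25),
                       TTP = mk_channel("TTP", 50, 15)),
       gt = binary_mask(lesion, spacing = c(1, 1, 1), subject_id = id,
                        channel = "GT"),
       head = binary_mask(head, spacing = c(1, 1, 1), subject_id = id),
       category = "lacunar/subcortical")
}
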