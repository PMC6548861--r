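toy_instance <- function(labels, probs) {
  n <- length(labels)
  list(gt = binary_mask(array(labels, c(n, 1, 1))),
       probs = probability_map(array(probs, c(n, 1, 1))))
}

test_that("THT0 maximises precision*recall over every achievable cut", {
  toy <- toy_instance(c(1, 1, 1, 0, 0, 0), c(0.9, 0.8, 0.4, 0.35, 0.2, 0.1))
  tuning <- tune_threshold_tht0(toy$gt, toy$probs)
  labels <- c(1, 1, 1, 0, 0, 0); probs <- c(0.9, 0.8, 0.4, 0.35, 0.2, 0.1)
  attained <- eval_objective(labels, probs, tuning$threshold, "pr")
  expect_equal(attained, oracle_best_objective(labels, probs, "pr"))
  expect_equal(attained, tuning$objective)

  # perfectly separable map: tuned threshold yields DSC = 1
  gt <- random_mask(c(6, 6, 6), 0.3)
  perfect <- probability_map(gt$voxels)
  t0 <- tune_threshold_tht0(gt, perfect)
  pred <- apply_threshold(perfect, t0$threshold)
  expect_equal(dice_coefficient(gt, pred), 1)
})

test_that("THT1 maximises TPR - FPR and degrades gracefully", {
  toy <- toy_instance(c(1, 1, 1, 0, 0, 0), c(0.9, 0.8, 0.4, 0.35, 0.2, 0.1))
  tuning <- tune_threshold_tht1(toy$gt, toy$probs)
  labels <- c(1, 1, 1, 0, 0, 0); probs <- c(0.9, 0.8, 0.4, 0.35, 0.2, 0.1)
  attained <- eval_objective(labels, probs, tuning$threshold, "roc")
  expect_equal(attained, oracle_best_objective(labels, probs, "roc"))

  gt <- random_mask(c(6, 6, 6), 0.3)
  perfect <- probability_map(gt$voxels)
  t1 <- tune_threshold_tht1(gt, perfect)
  expect_equal(t1$objective, 1)  # TPR - FPR = 1 at the tuned cut

  flat <- toy_instance(c(1, 0, 1, 0), c(0.5, 0.5, 0.5, 0.5))
  expect_warning(tf <- tune_threshold_tht1(flat$gt, flat$probs),
                 "uninformative")
  expect_equal(tf$threshold, 0.5)
})

test_that("tuned thresholds beat a dense 1e-3 grid on random instances", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    labels <- as.double(runif(n) < 0.4)
    if (sum(labels) %in% c(0, n)) next
    probs <- round(pmin(pmax(labels * runif(1, 0.2, 0.7) +
                               runif(n, 0, 0.6), 0), 1), 3)
    toy <- toy_instance(labels, probs)
    t0 <- tune_threshold_tht0(toy$gt, toy$probs)
    expect_gte(eval_objective(labels, probs, t0$threshold, "pr") + 1e-12,
               oracle_best_objective(labels, probs, "pr"))
    t1 <- suppressWarnings(tune_threshold_tht1(toy$gt, toy$probs))
    expect_gte(eval_objective(labels, probs, t1$threshold, "roc") + 1e-12,
               oracle_best_objective(labels, probs, "roc"))
  }
})

test_that("pooled tuning concatenates subjects and rejects one-class pools", {
  g1 <- binary_mask(array(c(1, 1, 0, 0), c(4, 1, 1)))
  g2 <- binary_mask(array(c(1, 0, 0, 0), c(4, 1, 1)))
  p1 <- probability_map(array(c(0.9, 0.6, 0.4, 0.1), c(4, 1, 1)))
  p2 <- probability_map(array(c(0.7, 0.3, 0.2, 0.1), c(4, 1, 1)))
  pooled <- tune_threshold_tht0(list(g1, g2), list(p1, p2))
  labels <- c(1, 1, 0, 0, 1, 0, 0, 0)
  probs <- c(0.9, 0.6, 0.4, 0.1, 0.7, 0.3, 0.2, 0.1)
  expect_equal(eval_objective(labels, probs, pooled$threshold, "pr"),
               oracle_best_objective(labels, probs, "pr"))

  all_pos <- binary_mask(array(1, c(4, 1, 1)))
  expect_error(tune_threshold_tht0(all_pos, p1), "both classes")
  expect_error(tune_threshold_tht0(list(g1), list(p1, p2)), "align")
})

test_that("ROC agreement with an independent curve implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  labels <- as.double(runif(300) < 0.3)
  probs <- pmin(pmax(labels * 0.3 + runif(300, 0, 0.7), 0), 1)
  toy <- toy_instance(labels, probs)
  t1 <- tune_threshold_tht1(toy$gt, toy$probs)
  roc <- pROC::roc(labels, probs, quiet = TRUE)
  youden <- max(roc$sensitivities + roc$specificities - 1)
  expect_equal(t1$objective, youden, tolerance = 1e-12)
})

test_that("thresholding is strict and respects its bounds", {
  fg <- array(c(0.3, 0.5, 0.7, 0), c(4, 1, 1))
  pm <- probability_map(fg)
  expect_equal(as.vector(apply_threshold(pm, 0.3)$voxels), c(0, 1, 1, 0))
  expect_equal(as.vector(apply_threshold(pm, 0)$voxels), c(1, 1, 1, 0))
  expect_equal(sum(apply_threshold(pm, 1)$voxels), 0)
  expect_error(apply_threshold(pm, 1.1), "\\[0, 1\\]")
})

test_that("closing-iteration tuning averages per-subject optima half-up", {
  # construct predictions whose best closing iteration count is known:
  # a solid block with holes of increasing size
  make_case <- function(hole) {
    gt_arr <- array(0, c(18, 18, 18)); gt_arr[4:15, 4:15, 4:15] <- 1
    pred <- gt_arr
    h <- 9 + seq_len(hole) - 1
    pred[h, 9, 9] <- 0
    list(gt = binary_mask(gt_arr), pred = binary_mask(pred))
  }
  cases <- lapply(c(1, 1, 3), make_case)
  gts <- lapply(cases, `[[`, "gt")
  preds <- lapply(cases, `[[`, "pred")
  cfg <- tune_closing_iterations(gts, preds, se_radius = 1, max_iter = 4)
  # per-subject optima found by sweeping the public closing function
  sweep_opt <- vapply(cases, function(cs) {
    d <- vapply(1:4, function(it) {
      dice_coefficient(cs$gt, binary_close(cs$pred, 1, it))
    }, numeric(1))
    which.max(d)
  }, integer(1))
  expect_identical(cfg$per_subject_optima, as.integer(sweep_opt))
  expect_equal(cfg$iterations, as.integer(floor(mean(sweep_opt) + 0.5)))

  single <- tune_closing_iterations(gts[1], preds[1], se_radius = 1)
  expect_equal(single$iterations, single$per_subject_optima[1])
  expect_error(tune_closing_iterations(list(), list()), "empty")
})

test_that("tuning warns when closing never helps", {
  gt_arr <- array(0, c(12, 12, 12)); gt_arr[6, 6, 6] <- 1
  pred <- array(0, c(12, 12, 12)); pred[6, 6, 6] <- 1; pred[6, 6, 8] <- 1
  expect_warning(cfg <- tune_closing_iterations(binary_mask(gt_arr),
                                                binary_mask(pred),
                                                se_radius = 1),
                 "not be beneficial")
  expect_equal(cfg$iterations, 1L)
})

test_that("negative-voxel subsampling keeps positives and stays sane", {
  set.seed(91)
  labels <- c(rep(1, 20), rep(0, 2000))
  probs <- pmin(pmax(labels * 0.5 + runif(2020, 0, 0.5), 0), 1)
  gt <- binary_mask(array(labels, c(2020, 1, 1)))
  pm <- probability_map(array(probs, c(2020, 1, 1)))
  full <- tune_threshold_tht0(gt, pm)
  sub <- tune_threshold_tht0(gt, pm, max_negatives = 300, seed = 2)
  expect_equal(max(sub$curve_points$y * sub$curve_points$x), sub$objective)
  expect_lt(abs(sub$threshold - full$threshold), 0.2)
  # subsampling is deterministic in its seed
  sub2 <- tune_threshold_tht0(gt, pm, max_negatives = 300, seed = 2)
  expect_identical(sub$threshold, sub2$threshold)
})

test_that("tuning curves plot without error", {
  gt <- random_mask(c(6, 6, 6), 0.3)
  fg <- pmin(pmax(gt$voxels * 0.5 + runif(216, 0, 0.5), 0), 1)
  tuning <- tune_threshold_tht0(gt, probability_map(array(fg, c(6, 6, 6))))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(tuning))
})
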