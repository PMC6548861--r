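test_that("confusion counts match hand counts and region restriction", {
  gt <- binary_mask(array(c(1, 1, 1, 0, 0, 0), c(6, 1, 1)))
  pred <- binary_mask(array(c(1, 1, 0, 1, 0, 0), c(6, 1, 1)))
  expect_equal(confusion_counts(gt, pred),
               c(TP = 2, TN = 2, FP = 1, FN = 1))
  expect_equal(sum(confusion_counts(gt, pred)), 6)

  same <- confusion_counts(gt, gt)
  expect_equal(same[["FP"]] + same[["FN"]], 0)
  compl <- binary_mask(array(1 - gt$voxels, dim(gt$voxels)))
  opp <- confusion_counts(gt, compl)
  expect_equal(opp[["TP"]] + opp[["TN"]], 0)

  region <- binary_mask(array(c(1, 1, 0, 0, 1, 1), c(6, 1, 1)))
  expect_equal(sum(confusion_counts(gt, pred, region)), 4)

  other <- binary_mask(array(0, c(5, 1, 1)))
  expect_error(confusion_counts(gt, other), "grid")
})

test_that("scalar metrics agree exactly with the contingency-table oracle", {
  m <- scalar_metrics(c(TP = 2, TN = 2, FP = 1, FN = 1))
  expect_equal(m[["TPR"]], 2 / 3)
  expect_equal(m[["PPV"]], 2 / 3)
  expect_equal(m[["DSC"]], 2 / 3)
  expect_equal(m[["ACC"]], 2 / 3)
  expect_equal(m[["MCC"]], 1 / 3)

  set.seed(41)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    g <- as.double(runif(n) < runif(1, 0.1, 0.9))
    p <- as.double(runif(n) < runif(1, 0.1, 0.9))
    counts <- confusion_counts(binary_mask(array(g, c(n, 1, 1))),
                               binary_mask(array(p, c(n, 1, 1))))
    got <- scalar_metrics(counts)
    want <- oracle_metrics(g, p)
    expect_identical(unname(got), unname(want[names(got)]))
  }
})

test_that("degenerate confusion tables follow the stated conventions", {
  perfect <- scalar_metrics(c(TP = 5, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("DSC", "MCC", "ACC")]), c(1, 1, 1))
  empty_pred <- scalar_metrics(c(TP = 0, TN = 10, FP = 0, FN = 5))
  expect_equal(unname(empty_pred[c("TPR", "DSC", "PPV", "MCC")]),
               c(0, 0, 0, 0))
  both_empty <- scalar_metrics(c(TP = 0, TN = 8, FP = 0, FN = 0))
  expect_equal(both_empty[["DSC"]], 1)
  expect_error(scalar_metrics(c(TP = -1, TN = 1, FP = 0, FN = 0)),
               "nonnegative")
})

test_that("MCC is centred on zero for independent predictions", {
  set.seed(59)
  n <- 200
  mccs <- replicate(400, {
    g <- as.double(runif(n) < 0.3)
    p <- as.double(runif(n) < 0.3)  # independent at gt prevalence
    scalar_metrics(confusion_counts(binary_mask(array(g, c(n, 1, 1))),
                                    binary_mask(array(p, c(n, 1, 1)))))[["MCC"]]
  })
  expect_lt(abs(mean(mccs)), 3 * sd(mccs) / sqrt(length(mccs)))
})

test_that("Dice equals its set-theoretic definition", {
  set.seed(61)
  for (i in 1:50) {
    a <- random_mask(c(5, 5, 5), runif(1, 0, 0.8))
    b <- random_mask(c(5, 5, 5), runif(1, 0, 0.8))
    inter <- sum(a$voxels * b$voxels)
    denom <- sum(a$voxels) + sum(b$voxels)
    expect_equal(dice_coefficient(a, b), if (denom == 0) 1 else 2 * inter / denom)
  }
})

test_that("Hausdorff distance matches the exhaustive oracle in mm", {
  g <- array(0, c(6, 6, 6)); g[1, 1, 1] <- 1
  p <- array(0, c(6, 6, 6)); p[4, 5, 1] <- 1
  expect_equal(hausdorff_distance(binary_mask(g), binary_mask(p)), 5)

  gs <- binary_mask(g, spacing = c(2, 2, 2))
  ps <- binary_mask(p, spacing = c(2, 2, 2))
  expect_equal(hausdorff_distance(gs, ps), 10)  # spacing-scaled

  set.seed(71)
  for (i in 1:40) {
    a <- random_mask(c(6, 6, 6), runif(1, 0.05, 0.5))
    b <- random_mask(c(6, 6, 6), runif(1, 0.05, 0.5))
    if (sum(a$voxels) == 0 || sum(b$voxels) == 0) next
    expect_equal(hausdorff_distance(a, b), oracle_hausdorff(a, b))
    expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
  }
  expect_equal(hausdorff_distance(a, a), 0)
})

test_that("Hausdorff conventions for empty masks", {
  e <- binary_mask(array(0, c(4, 4, 4)))
  m <- random_mask(c(4, 4, 4), 0.5)
  expect_equal(hausdorff_distance(e, e), 0)
  expect_true(is.na(hausdorff_distance(e, m)))
  expect_true(is.na(hausdorff_distance(m, e)))
})

test_that("Landis-Koch bands follow the printed intervals", {
  table_cases <- data.frame(
    dsc = c(-0.1, 0, 0.1, 0.20, 0.21, 0.34, 0.40, 0.45, 0.60, 0.61, 0.80,
            0.81, 1),
    band = c("Poor", "Poor", "Slight", "Slight", "Fair", "Fair", "Fair",
             "Moderate", "Moderate", "Substantial", "Substantial",
             "Almost perfect", "Almost perfect"))
  expect_identical(landis_koch(table_cases$dsc), table_cases$band)
})

test_that("aggregation yields means, CIs, the 'all' stratum and fold means", {
  records <- data.frame(
    subject_id = sprintf("s%d", 1:4),
    DSC = c(0.2, 0.4, 0.6, 0.8), HD = c(10, NA, 30, 50),
    category = c("a", "a", "b", "b"), fold_id = c(1, 1, 2, 2),
    postproc_step = "Base")
  s <- aggregate_metrics(records, by = "postproc_step", include_all = FALSE)
  dsc_row <- s[s$metric == "DSC", ]
  expect_equal(dsc_row$mean, 0.5)
  expect_equal(dsc_row$ci_high - dsc_row$mean,
               1.96 * sd(c(0.2, 0.4, 0.6, 0.8)) / 2)
  hd_row <- s[s$metric == "HD", ]
  expect_equal(hd_row$n, 3)
  expect_equal(hd_row$n_excluded, 1)  # undefined HD excluded, counted

  single <- aggregate_metrics(records[1, ], by = "postproc_step",
                              include_all = FALSE)
  expect_equal(single$ci_low, single$mean)

  by_cat <- aggregate_metrics(records, by = c("postproc_step", "category"))
  expect_setequal(unique(by_cat$category), c("a", "b", "all"))
  all_dsc <- by_cat[by_cat$category == "all" & by_cat$metric == "DSC", ]
  expect_equal(all_dsc$mean, 0.5)

  by_fold <- aggregate_metrics(records, by = "postproc_step",
                               weight = "fold", include_all = FALSE)
  fold_dsc <- by_fold[by_fold$metric == "DSC", ]
  expect_equal(fold_dsc$mean, mean(c(mean(c(0.2, 0.4)), mean(c(0.6, 0.8)))))
})

test_that("Bland-Altman differences, sign and limits of agreement", {
  records <- data.frame(
    subject_id = c("s1", "s2"), gt_volume = c(100, 110),
    pred_volume = c(110, 100), postproc_step = "Base")
  ba <- bland_altman(records)
  expect_equal(ba$points$diff_volume, c(10, -10))  # pred - gt
  expect_equal(ba$points$avg_volume, c(105, 105))
  expect_equal(ba$summary$mean_diff, 0)
  expect_equal(ba$summary$loa_high, 1.96 * 10 * sqrt(2), tolerance = 1e-12)

  exact <- data.frame(subject_id = "s1", gt_volume = 50, pred_volume = 50,
                      postproc_step = "Base")
  ba0 <- bland_altman(exact)
  expect_equal(unlist(ba0$summary[c("mean_diff", "loa_low", "loa_high")]),
               c(mean_diff = 0, loa_low = 0, loa_high = 0))
})

test_that("metrics records carry volumes in mm^3 and category labels", {
  gt <- solid_sphere_mask(12, 3, spacing = c(2, 2, 2))
  rec <- metrics_record(gt, gt, category = "small cortical", fold_id = 2,
                        postproc_step = "FH")
  expect_equal(rec$gt_volume, sum(gt$voxels) * 8)
  expect_equal(rec$DSC, 1)
  expect_equal(rec$HD, 0)
  expect_equal(rec$postproc_step, "FH")
})
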