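test_that("5-fold splits partition 43 subjects into 9/9/9/8/8 test groups", {
  ids <- sprintf("sub%02d", 1:43)
  folds <- make_folds(ids, k = 5, seed = 4)
  sizes <- sort(vapply(folds, function(f) length(f$test_ids), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(9, 9, 9, 8, 8))
  # coverage and disjointness
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0)
  for (f in folds) {
    expect_equal(length(intersect(f$train_ids, f$val_ids)), 0)
    expect_equal(length(intersect(f$train_ids, f$test_ids)), 0)
    expect_equal(length(intersect(f$val_ids, f$test_ids)), 0)
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), ids)
  }
  # determinism
  expect_identical(folds, make_folds(ids, k = 5, seed = 4))
  expect_false(identical(folds, make_folds(ids, k = 5, seed = 5)))
  expect_error(make_folds(ids, k = 1), ">= 2")
  expect_error(make_folds(ids[1:3], k = 5), "exceed")
})

test_that("stratified folds spread categories across test groups", {
  ids <- sprintf("s%02d", 1:30)
  cats <- rep(c("a", "b", "c"), each = 10)
  folds <- make_folds(ids, k = 5, seed = 7, categories = cats)
  for (f in folds) {
    got <- table(cats[match(f$test_ids, ids)])
    expect_true(all(got == 2))  # 10 of each category over 5 folds
  }
})

small_cohort <- function(n = 6, seed = 3) {
  spec <- phantom_spec(shape = c(26, 26, 26), seed = seed)
  cats <- rep(c("big cortical/main artery", "lacunar/subcortical"),
              length.out = n)
  lapply(seq_len(n), function(i) {
    make_phantom(spec, sprintf("p%02d", i), category = cats[i],
                 seed = seed + i)
  })
}

test_that("an oracle segmenter drives the pipeline to perfect Dice", {
  cohort <- small_cohort(6)
  # identity working space isolates the pipeline plumbing from resampling
  cfg <- experiment_config(k = 3, seed = 2, max_iter = 2,
                           preprocess = preprocess_config(dF = 1))
  report <- suppressWarnings(run_experiment(cohort, oracle_segmenter(), cfg))
  expect_equal(length(report$failed_folds), 0)
  recs <- report$records
  expect_equal(nrow(recs), 6 * 4)  # every subject tested once, 4 steps
  exact <- recs[recs$postproc_step %in% c("Base", "THT0", "THT1"), ]
  expect_true(all(exact$DSC == 1))
  # closing an already-perfect mask can only add boundary voxels
  expect_true(all(recs$DSC[recs$postproc_step == "FH"] > 0.95))

  # with a downsampled working space the restored GT still overlaps well
  cfg07 <- experiment_config(k = 3, seed = 2, max_iter = 2,
                             preprocess = preprocess_config(dF = 0.7))
  rep07 <- suppressWarnings(run_experiment(cohort, oracle_segmenter(), cfg07))
  big <- rep07$records$category == "big cortical/main artery" &
    rep07$records$postproc_step == "Base"
  expect_true(all(rep07$records$DSC[big] > 0.9))
})

test_that("experiments are deterministic and leakage-guarded", {
  cohort <- small_cohort(6)
  seg <- degraded_segmenter(degradation_spec(hole_rate = 0.2, seed = 5))
  cfg <- experiment_config(k = 3, seed = 9, max_iter = 2, augment = TRUE)
  r1 <- suppressWarnings(run_experiment(cohort, seg, cfg))
  r2 <- suppressWarnings(run_experiment(cohort, seg, cfg))
  expect_identical(r1$records, r2$records)
  # every subject appears in exactly one test set
  expect_equal(sort(unique(r1$records$subject_id)),
               sprintf("p%02d", 1:6))
  expect_equal(nrow(r1$records), 6 * 4)
  # augmentation manifests never clone validation/test subjects
  for (fid in names(r1$manifests)) {
    man <- r1$manifests[[fid]]
    fold <- r1$folds[[as.integer(fid)]]
    clones <- man[!is.na(man$clone_of), ]
    expect_true(all(clones$clone_of %in% fold$train_ids))
    expect_true(all(clones$role == "train"))
  }
  # tuned parameters derive from the fold's validation subjects only
  for (fold in r1$folds) {
    tn <- r1$tunings[[as.character(fold$fold_id)]]
    expect_equal(tn$THT0$fold_id, fold$fold_id)
    expect_length(tn$FH$per_subject_optima, length(fold$val_ids))
  }
})

test_that("a failing segmenter marks its fold failed without killing the run", {
  cohort <- small_cohort(6)
  flaky <- function(prepped, fold, manifest = NULL) {
    if (fold$fold_id == 2) stop("segmenter exploded")
    oracle_segmenter()(prepped, fold, manifest)
  }
  warns <- testthat::capture_warnings(
    report <- run_experiment(cohort, flaky,
                             experiment_config(k = 3, seed = 2,
                                               max_iter = 2)))
  expect_match(warns, "fold 2 failed", all = FALSE)
  expect_equal(report$failed_folds, 2L)
  expect_lt(nrow(report$records), 6 * 4)
})

test_that("the reference segmenter never reads ground truth yet beats chance", {
  cohort <- small_cohort(4)
  # posioned gt: if the segmenter read test GT this would corrupt output
  cfg <- experiment_config(k = 2, seed = 6, max_iter = 2)
  report <- suppressWarnings(run_experiment(cohort, reference_segmenter(),
                                            cfg))
  base <- report$records[report$records$postproc_step == "Base", ]
  expect_true(mean(base$DSC) > 0)
})
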