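#' Deterministic k-fold splits with train/validation/test roles
#'
#' Shuffles the subjects with the given seed and partitions them into k
#' test groups whose sizes differ by at most one (43 subjects at k = 5
#' give groups of 9, 9, 9, 8 and 8); within each fold the remaining
#' subjects are split into validation and training sets. Every subject
#' appears in exactly one test set across the k folds.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param k number of folds (>= 2); default 5.
#' @param seed RNG seed; identical seeds give identical folds.
#' @param val_fraction fraction of each fold's non-test subjects used for
#'   validation (threshold/closing tuning); default 0.2.
#' @param categories optional per-subject category labels enabling
#'   category-stratified test groups (off unless supplied).
#' @return List of fold objects, each with \code{fold_id},
#'   \code{train_ids}, \code{val_ids}, \code{test_ids} and \code{seed}.
#' @export
make_folds <- function(subject_ids, k = 5, seed = 1, val_fraction = 0.2,
                       categories = NULL) {
  n <- length(subject_ids)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the number of subjects", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  assign_fold <- with_seed(derive_seed(seed, "folds"), {
    if (is.null(categories)) {
      shuffled <- sample(subject_ids)
      sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
      rep(seq_len(k), sizes)[match(subject_ids, shuffled)]
    } else {
      stopifnot(length(categories) == n)
      fold_of <- integer(n)
      slot <- 0L
      for (cat in unique(categories)) {
        members <- sample(which(categories == cat))
        for (m in members) {
          fold_of[m] <- (slot %% k) + 1L
          slot <- slot + 1L
        }
      }
      fold_of
    }
  })
  lapply(seq_len(k), function(f) {
    test_ids <- subject_ids[assign_fold == f]
    rest <- subject_ids[assign_fold != f]
    rest <- with_seed(derive_seed(seed, paste0("val/", f)), sample(rest))
    n_val <- max(1L, as.integer(round(val_fraction * length(rest))))
    list(fold_id = f, train_ids = sort(rest[-seq_len(n_val)]),
         val_ids = sort(rest[seq_len(n_val)]), test_ids = sort(test_ids),
         seed = seed)
  })
}

#' Experiment configuration for [run_experiment()]
#'
#' @param k number of cross-validation folds; default 5.
#' @param seed master seed for folds and any stochastic segmenter.
#' @param val_fraction validation fraction within each fold's non-test
#'   subjects; default 0.2.
#' @param preprocess a [preprocess_config()].
#' @param augment apply intensity-variance augmentation to each fold's
#'   training set (manifest-level; clones are materialised only when
#'   \code{materialize_clones} is TRUE).
#' @param augment_cfg an [augment_config()].
#' @param materialize_clones generate clone volumes (needed by segmenters
#'   that actually train); the bundled reference segmenters only need the
#'   manifest.
#' @param se_radius,max_iter closing-tuning parameters (FH step).
#' @param stratify_folds stratify test groups by lesion category.
#' @return A list of class \code{experiment_config}.
#' @export
experiment_config <- function(k = 5, seed = 1, val_fraction = 0.2,
                              preprocess = preprocess_config(),
                              augment = FALSE,
                              augment_cfg = augment_config(),
                              materialize_clones = FALSE,
                              se_radius = 3, max_iter = 5,
                              stratify_folds = FALSE) {
  structure(list(k = k, seed = seed, val_fraction = val_fraction,
                 preprocess = preprocess, augment = augment,
                 augment_cfg = augment_cfg,
                 materialize_clones = materialize_clones,
                 se_radius = se_radius, max_iter = max_iter,
                 stratify_folds = stratify_folds),
            class = "experiment_config")
}

#' Bundled segmenters for exercising the pipeline
#'
#' These lightweight callables satisfy the segmenter contract — given the
#' pre-processed cohort and a fold's subject roles, return a working-space
#' [probability_map()] for each requested validation/test subject — so the
#' full pipeline can be run with no CNN. \code{oracle_segmenter} returns
#' the (working-space) ground truth as probabilities;
#' \code{degraded_segmenter} corrupts it per a [degradation_spec()]
#' (a constructed test double, useful to study post-processing);
#' \code{reference_segmenter} is an honest non-learning baseline that
#' smooths and combines the intensity channels, never touching any ground
#' truth. None of them is a neural network.
#'
#' @param spec a [degradation_spec()] for \code{degraded_segmenter}.
#' @return A function \code{(prepped, fold, manifest) -> named list of
#'   probability maps} for the fold's validation and test subjects.
#' @export
oracle_segmenter <- function() {
  function(prepped, fold, manifest = NULL) {
    wanted <- c(fold$val_ids, fold$test_ids)
    out <- lapply(wanted, function(id) {
      gtw <- prepped[[id]]$gt_working
      probability_map(gtw$voxels, affine = gtw$affine, subject_id = id,
                      transform = gtw$transform)
    })
    names(out) <- wanted
    out
  }
}

#' @rdname oracle_segmenter
#' @export
degraded_segmenter <- function(spec = degradation_spec()) {
  force(spec)
  function(prepped, fold, manifest = NULL) {
    wanted <- c(fold$val_ids, fold$test_ids)
    out <- lapply(wanted, function(id) {
      p <- prepped[[id]]
      pm <- degrade_gt_to_probs(p$gt_working, spec, head = p$mask)
      pm$transform <- p$gt_working$transform
      pm
    })
    names(out) <- wanted
    out
  }
}

#' @param fg_signs named vector of expected lesion contrast signs per
#'   channel for \code{reference_segmenter} (+1: lesion brighter).
#' @param smooth_fwhm smoothing FWHM in mm before combining channels.
#' @param gain logistic gain applied to the combined z-score.
#' @rdname oracle_segmenter
#' @export
reference_segmenter <- function(fg_signs = c(ADC = -1, MTT = 1, rCBF = -1),
                                smooth_fwhm = 3, gain = 1.5) {
  function(prepped, fold, manifest = NULL) {
    wanted <- c(fold$val_ids, fold$test_ids)
    out <- lapply(wanted, function(id) {
      p <- prepped[[id]]
      score <- NULL
      used <- 0
      for (ch in names(fg_signs)) {
        vol <- find_channel(p$channels, ch)
        if (is.null(vol)) next
        sigma <- smooth_fwhm / (2 * sqrt(2 * log(2))) / vol$spacing
        sm <- gauss_blur(vol$voxels, sigma)
        score <- if (is.null(score)) fg_signs[[ch]] * sm
                 else score + fg_signs[[ch]] * sm
        used <- used + 1
      }
      if (used == 0) stop("reference_segmenter: no usable channels", call. = FALSE)
      fg <- stats::plogis(gain * score / used)
      fg[p$mask$voxels == 0] <- 0
      gtw <- p$gt_working
      probability_map(fg, affine = gtw$affine, subject_id = id,
                      transform = gtw$transform)
    })
    names(out) <- wanted
    out
  }
}

prep_cohort <- function(cohort, pre_cfg) {
  prepped <- lapply(cohort, function(subj) {
    pp <- preprocess_subject(subj$channels, pre_cfg)
    gt_working <- resample_to_spacing(subj$gt, pre_cfg$target_spacing,
                                      pre_cfg$dF)
    list(channels = pp$channels, mask = pp$mask, gt_working = gt_working,
         gt_native = subj$gt, category = subj$category,
         subject_id = subj$subject_id)
  })
  names(prepped) <- vapply(cohort, `[[`, character(1), "subject_id")
  prepped
}

#' Run a full cross-validated post-processing experiment
#'
#' The orchestrator: pre-processes every subject to the working space,
#' builds k folds, optionally augments each fold's training manifest with
#' intensity-variance clones (clones of validation/test subjects are never
#' created), calls the pluggable segmenter for validation and test
#' probability maps, restores all outputs to native space, tunes THT0,
#' THT1 and the FH closing iteration count on the fold's validation
#' subjects only, applies all four post-processing variants (Base = 0.5
#' threshold, THT0, THT1, FH = closing of Base) to the fold's test
#' subjects, and evaluates everything in native space.
#'
#' @param cohort list of subjects, each a list with \code{subject_id},
#'   \code{channels} (named native-space [subject_volume()]s including
#'   TTP), \code{gt} (native [binary_mask()]) and \code{category} — the
#'   layout produced by [simulate_cohort()].
#' @param segmenter a segmenter callable (see [oracle_segmenter()]).
#' @param config an [experiment_config()].
#' @return An object of class \code{experiment_report}: per-subject
#'   \code{records}, per-fold \code{tunings} and \code{manifests},
#'   \code{folds}, \code{failed_folds} and the \code{config}.
#' @export
run_experiment <- function(cohort, segmenter, config = experiment_config()) {
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  categories <- vapply(cohort, function(s) s$category %||% NA_character_,
                       character(1))
  names(categories) <- ids
  prepped <- prep_cohort(cohort, config$preprocess)
  folds <- make_folds(ids, k = config$k, seed = config$seed,
                      val_fraction = config$val_fraction,
                      categories = if (config$stratify_folds) categories
                                   else NULL)
  records <- list()
  tunings <- list()
  manifests <- list()
  failed <- integer(0)
  for (fold in folds) {
    res <- tryCatch(run_fold(prepped, segmenter, fold, categories, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("fold %d failed: %s", fold$fold_id,
                      conditionMessage(res)), call. = FALSE)
      failed <- c(failed, fold$fold_id)
      next
    }
    records[[length(records) + 1L]] <- res$records
    tunings[[as.character(fold$fold_id)]] <- res$tuning
    manifests[[as.character(fold$fold_id)]] <- res$manifest
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  structure(list(records = records, tunings = tunings, manifests = manifests,
                 folds = folds, failed_folds = failed, config = config),
            class = "experiment_report")
}

run_fold <- function(prepped, segmenter, fold, categories, config) {
  roles <- data.frame(
    subject_id = c(fold$train_ids, fold$val_ids, fold$test_ids),
    role = c(rep("train", length(fold$train_ids)),
             rep("validation", length(fold$val_ids)),
             rep("test", length(fold$test_ids))),
    stringsAsFactors = FALSE)
  manifest <- NULL
  if (isTRUE(config$augment)) {
    manifest <- augment_dataset(roles, config$augment_cfg)
    if (isTRUE(config$materialize_clones)) {
      for (id in fold$train_ids) {
        for (ci in seq_len(config$augment_cfg$clones_number)) {
          prepped[[paste0(id, "_clone", ci)]] <- within_clone(
            prepped[[id]], config$augment_cfg, ci)
        }
      }
    }
  }
  probs_work <- segmenter(prepped, fold, manifest)
  # restore everything to native space before any post-processing, so that
  # tuning and evaluation happen in the subjects' original dimensional space
  probs_native <- lapply(c(fold$val_ids, fold$test_ids), function(id) {
    restore_to_native(probs_work[[id]], prepped[[id]]$gt_native)
  })
  names(probs_native) <- c(fold$val_ids, fold$test_ids)
  gts_val <- lapply(fold$val_ids, function(id) prepped[[id]]$gt_native)
  tht0 <- tune_threshold_tht0(gts_val, probs_native[fold$val_ids],
                              fold_id = fold$fold_id)
  tht1 <- tune_threshold_tht1(gts_val, probs_native[fold$val_ids],
                              fold_id = fold$fold_id)
  base_val <- lapply(fold$val_ids, function(id) {
    apply_threshold(probs_native[[id]], 0.5)
  })
  fh <- tune_closing_iterations(gts_val, base_val,
                                se_radius = config$se_radius,
                                max_iter = config$max_iter,
                                fold_id = fold$fold_id)
  recs <- lapply(fold$test_ids, function(id) {
    gt <- prepped[[id]]$gt_native
    pm <- probs_native[[id]]
    base <- apply_threshold(pm, 0.5)
    steps <- list(
      Base = base,
      THT0 = apply_threshold(pm, tht0$threshold),
      THT1 = apply_threshold(pm, tht1$threshold),
      FH = binary_close(base, radius = fh$se_radius,
                        iterations = fh$iterations))
    do.call(rbind, lapply(names(steps), function(st) {
      metrics_record(gt, steps[[st]], category = categories[[id]],
                     fold_id = fold$fold_id, postproc_step = st)
    }))
  })
  list(records = do.call(rbind, recs),
       tuning = list(THT0 = tht0, THT1 = tht1, FH = fh),
       manifest = manifest)
}

within_clone <- function(prepped_subject, cfg, clone_index) {
  cloned <- intensity_variance_clone(prepped_subject$channels,
                                     prepped_subject$gt_working, cfg,
                                     clone_index = clone_index)
  out <- prepped_subject
  out$channels <- cloned
  out$subject_id <- cloned[[1]]$subject_id
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d folds (%d failed), %d records\n",
              length(x$folds), length(x$failed_folds),
              if (is.null(x$records)) 0L else nrow(x$records)))
  if (!is.null(x$records)) {
    s <- aggregate_metrics(x$records, by = "postproc_step",
                           include_all = FALSE)
    print(s[s$metric %in% c("DSC", "TPR", "PPV", "HD"),
            c("postproc_step", "metric", "n", "mean", "ci_low", "ci_high")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.experiment_report <- function(object, by = c("postproc_step"), ...) {
  aggregate_metrics(object$records, by = by)
}
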