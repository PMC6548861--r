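#' Augmentation configuration
#'
#' Parameters for offline intensity-variance cloning and the two online
#' augmentations (X-axis reflection and global intensity jitter
#' \eqn{I' = (I + s) m}).
#'
#' @param clones_number clones generated per training subject; default 1.
#' @param seed master RNG seed; per-subject streams are derived from it so
#'   adding subjects never perturbs existing clones.
#' @param reflect_prob probability of reflecting a volume along the X axis
#'   during online augmentation; default 0.5.
#' @param shift_sigma SD of the additive shift \eqn{s \sim N(0, \sigma^2)};
#'   default 0.05.
#' @param multi_sigma SD of the multiplicative factor
#'   \eqn{m \sim N(1, \sigma^2)}; default 0.01.
#' @return A list of class \code{augment_config}.
#' @export
augment_config <- function(clones_number = 1, seed = 1, reflect_prob = 0.5,
                           shift_sigma = 0.05, multi_sigma = 0.01) {
  if (clones_number < 0) stop("clones_number must be >= 0", call. = FALSE)
  if (reflect_prob < 0 || reflect_prob > 1) {
    stop("reflect_prob must be in [0, 1]", call. = FALSE)
  }
  if (shift_sigma < 0 || multi_sigma < 0) {
    stop("sigmas must be >= 0", call. = FALSE)
  }
  structure(list(clones_number = as.integer(clones_number), seed = seed,
                 reflect_prob = reflect_prob, shift_sigma = shift_sigma,
                 multi_sigma = multi_sigma),
            class = "augment_config")
}

#' Intensity-variance clone of a subject
#'
#' Creates one augmentation clone: in every channel independently, the
#' voxels inside the lesion label are replaced by i.i.d. draws from a
#' Gaussian whose mean and (population) SD equal that channel's in-ROI
#' statistics; voxels outside the ROI are bit-identical to the original.
#' This perturbs the lesion's intensity pattern while keeping its overall
#' appearance recognisable, emulating the intensity inhomogeneity seen
#' within real ischaemic lesions.
#'
#' @param channels named list of [subject_volume()]s on one grid.
#' @param label lesion [binary_mask()] (the ROI) on the same grid.
#' @param cfg an [augment_config()]; its \code{seed} makes the clone
#'   deterministic.
#' @param clone_index index of this clone (>= 1), folded into the RNG
#'   stream so multiple clones of one subject differ.
#' @return Named list of cloned [subject_volume()]s.
#' @export
intensity_variance_clone <- function(channels, label, cfg = augment_config(),
                                     clone_index = 1) {
  if (inherits(channels, "subject_volume")) channels <- list(channels)
  stop_if_grid_mismatch(channels[[1]], label, "channels and label")
  roi <- label$voxels > 0
  n_roi <- sum(roi)
  if (n_roi == 0) stop("label is empty; nothing to clone", call. = FALSE)
  sid <- channels[[1]]$subject_id
  out <- channels
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    vals <- ch$voxels[roi]
    mu <- mean(vals)
    sdv <- sqrt(sum((vals - mu)^2) / n_roi)
    seed <- derive_seed(cfg$seed,
                        paste("clone", sid, ch$channel, clone_index, sep = "/"))
    draws <- with_seed(seed, {
      if (sdv > 0) stats::rnorm(n_roi, mu, sdv) else rep(mu, n_roi)
    })
    if (sdv == 0) {
      warning(sprintf("channel %s: single-valued ROI (SD = 0); clone equals ROI mean",
                      ch$channel), call. = FALSE)
    }
    cl <- ch
    cl$voxels[roi] <- draws
    cl$subject_id <- paste0(sid, "_clone", clone_index)
    out[[i]] <- cl
  }
  out
}

#' Build an augmented training manifest
#'
#' Expands a cohort manifest with intensity-variance clones for the
#' training-role subjects only. Cloning validation or test subjects is
#' meaningless (they are never trained on) and is refused, so clones can
#' never leak across the train/validation/test boundary: 43 training
#' subjects with one clone each give an 86-entry training manifest.
#'
#' @param subjects data frame with columns \code{subject_id} and \code{role}
#'   (\code{"train"}, \code{"validation"} or \code{"test"}).
#' @param cfg an [augment_config()].
#' @param ids optional subject ids to clone; defaults to all train-role
#'   subjects. Requesting a non-train subject is a policy error.
#' @return Data frame with columns \code{subject_id}, \code{clone_of}
#'   (\code{NA} for originals) and \code{role}.
#' @export
augment_dataset <- function(subjects, cfg = augment_config(), ids = NULL) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "role") %in% names(subjects)))
  if (!all(subjects$role %in% c("train", "validation", "test"))) {
    stop("roles must be train/validation/test", call. = FALSE)
  }
  train_ids <- subjects$subject_id[subjects$role == "train"]
  if (is.null(ids)) {
    ids <- train_ids
  } else if (!all(ids %in% train_ids)) {
    bad <- setdiff(ids, train_ids)
    stop(sprintf("refusing to clone non-training subject(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  manifest <- data.frame(subject_id = subjects$subject_id,
                         clone_of = NA_character_,
                         role = subjects$role,
                         stringsAsFactors = FALSE)
  if (cfg$clones_number > 0 && length(ids) > 0) {
    clones <- expand.grid(clone = seq_len(cfg$clones_number),
                          clone_of = ids, stringsAsFactors = FALSE)
    manifest <- rbind(manifest, data.frame(
      subject_id = paste0(clones$clone_of, "_clone", clones$clone),
      clone_of = clones$clone_of,
      role = "train", stringsAsFactors = FALSE))
  }
  rownames(manifest) <- NULL
  manifest
}

#' Reflect a volume along the X axis
#'
#' Mirrors the grid along the first spatial axis (left-right). One of the
#' two online augmentations, applied with 50\% probability during training.
#'
#' @param vol a [subject_volume()], [binary_mask()] or plain 3-D array.
#' @return Same type, mirrored.
#' @export
reflect_x <- function(vol) {
  flip <- function(a) {
    out <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
    dim(out) <- dim(a)
    out
  }
  if (inherits(vol, "subject_volume")) {
    vol$voxels <- flip(vol$voxels)
    vol
  } else {
    flip(vol)
  }
}

#' Global intensity jitter I' = (I + s) * m
#'
#' The second online augmentation: one additive shift
#' \eqn{s \sim N(0, \code{shift_sigma}^2)} and one multiplicative factor
#' \eqn{m \sim N(1, \code{multi_sigma}^2)} are drawn per call and applied to
#' the whole volume.
#'
#' @param vol a [subject_volume()] or 3-D array.
#' @param cfg an [augment_config()].
#' @param seed optional seed for a reproducible draw; \code{NULL} uses the
#'   current RNG stream.
#' @return Same type as input, jittered.
#' @export
intensity_jitter <- function(vol, cfg = augment_config(), seed = NULL) {
  sm <- with_seed(seed, c(stats::rnorm(1, 0, cfg$shift_sigma),
                          stats::rnorm(1, 1, cfg$multi_sigma)))
  apply_jitter <- function(a) (a + sm[1]) * sm[2]
  if (inherits(vol, "subject_volume")) {
    vol$voxels <- apply_jitter(vol$voxels)
    vol
  } else {
    apply_jitter(vol)
  }
}
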