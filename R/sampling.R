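#' Per-class error (sampling weight) map
#'
#' For each class c, the raw map is the voxelwise squared error between the
#' class indicator of the ground truth and the predicted class probability,
#' \eqn{(\mathbf{1}[gt = c] - p_c)^2}; each class map is then z-normalised
#' over the whole grid (per subject, per class) for homogeneity between
#' subjects. Patch-based trainers draw more image segments where these
#' weights are larger, focusing learning on regions the model got wrong. A
#' raw map with zero variance (e.g. a perfect prediction) is returned as all
#' zeros with a warning.
#'
#' @param gt ground-truth [binary_mask()].
#' @param probs [probability_map()] on the same grid.
#' @param normalize z-normalise the raw squared errors (default TRUE); raw
#'   maps are also accepted downstream.
#' @return A list of class \code{weight_map} with elements \code{fg},
#'   \code{bg} (3-D weight grids), \code{norm_record} (pre-normalisation
#'   mean/SD per class, so raw maps are recoverable), and grid metadata.
#' @export
error_map <- function(gt, probs, normalize = TRUE) {
  stop_if_grid_mismatch(gt, probs, "ground truth and probability map")
  raw_fg <- (gt$voxels - probs$fg)^2
  raw_bg <- ((1 - gt$voxels) - probs$bg)^2
  znorm <- function(raw, class_name) {
    mu <- mean(raw)
    sdv <- sqrt(mean((raw - mu)^2))
    if (!normalize) {
      return(list(map = raw, mean = mu, sd = sdv, normalized = FALSE))
    }
    if (sdv == 0) {
      warning(sprintf("%s error map has zero variance; returned as zeros",
                      class_name), call. = FALSE)
      return(list(map = array(0, dim(raw)), mean = mu, sd = 0,
                  normalized = TRUE))
    }
    list(map = (raw - mu) / sdv, mean = mu, sd = sdv, normalized = TRUE)
  }
  zf <- znorm(raw_fg, "foreground")
  zb <- znorm(raw_bg, "background")
  structure(list(fg = zf$map, bg = zb$map,
                 norm_record = list(
                   fg = list(mean = zf$mean, sd = zf$sd),
                   bg = list(mean = zb$mean, sd = zb$sd),
                   normalized = normalize),
                 affine = gt$affine, spacing = gt$spacing,
                 subject_id = gt$subject_id),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map> %s  %s voxels (%s)\n", x$subject_id,
              paste(dim(x$fg), collapse = "x"),
              if (isTRUE(x$norm_record$normalized)) "z-normalised" else "raw"))
  invisible(x)
}

#' Draw patch centres weighted by an error map
#'
#' Samples voxel indices with probability proportional to the (shifted)
#' weights inside a valid region, so segments are extracted more often
#' where the weights are bigger. Nonnegative (raw) weights are used
#' directly; z-normalised weights can be negative, in which case the
#' in-region weights are affinely shifted so the minimum maps to a small
#' positive floor (1e-6 of the shifted maximum). If all in-region weights
#' are equal the sampler falls back to uniform with a warning.
#'
#' @param weights a 3-D weight grid, or a \code{weight_map} (its foreground
#'   class is used).
#' @param valid_region [binary_mask()] (or 0/1 array) restricting candidate
#'   centres; must be nonempty.
#' @param n number of centres to draw (>= 1).
#' @param seed RNG seed making the draw deterministic.
#' @return Integer matrix \code{n x 3} of 1-based voxel indices.
#' @export
weighted_sample_centers <- function(weights, valid_region, n, seed = 1) {
  if (inherits(weights, "weight_map")) weights <- weights$fg
  region <- if (inherits(valid_region, "binary_mask")) valid_region$voxels
            else valid_region
  if (!identical(dim(weights), dim(region))) {
    stop("weights and valid_region must share a grid", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  idx <- which(region > 0)
  if (length(idx) == 0) stop("valid_region is empty", call. = FALSE)
  w <- weights[idx]
  if (max(w) == min(w)) {
    warning("all in-region weights equal; falling back to uniform sampling",
            call. = FALSE)
    p <- rep(1, length(idx))
  } else if (min(w) < 0) {
    # z-scored weights: shift so the minimum maps to a small positive floor
    shifted <- w - min(w)
    p <- shifted + 1e-6 * max(shifted)
  } else {
    p <- w  # nonnegative raw weights are used as-is
  }
  picks <- with_seed(seed,
                     sample.int(length(idx), n, replace = TRUE, prob = p))
  arrayInd(idx[picks], dim(weights))
}

#' Balanced foreground/background patch centres
#'
#' The default sampling scheme of patch-based segmenters: each draw picks
#' foreground (the lesion label) or background (the intracranial mask minus
#' the label) with probability 0.5, then a uniformly random voxel of that
#' region.
#'
#' @param gt lesion [binary_mask()] (foreground region).
#' @param brain_mask intracranial [binary_mask()].
#' @param n number of centres to draw.
#' @param seed RNG seed.
#' @return Integer matrix \code{n x 3} of 1-based voxel indices, with a
#'   logical attribute \code{"foreground"} flagging each draw's region.
#' @export
uniform_fg_bg_centers <- function(gt, brain_mask, n, seed = 1) {
  stop_if_grid_mismatch(gt, brain_mask, "label and brain mask")
  fg_idx <- which(gt$voxels > 0)
  bg_idx <- which(brain_mask$voxels > 0 & gt$voxels == 0)
  if (length(fg_idx) == 0 || length(bg_idx) == 0) {
    stop("foreground or background region is empty", call. = FALSE)
  }
  res <- with_seed(seed, {
    is_fg <- stats::runif(n) < 0.5
    pick <- integer(n)
    pick[is_fg] <- fg_idx[sample.int(length(fg_idx), sum(is_fg), replace = TRUE)]
    pick[!is_fg] <- bg_idx[sample.int(length(bg_idx), sum(!is_fg), replace = TRUE)]
    list(pick = pick, is_fg = is_fg)
  })
  out <- arrayInd(res$pick, dim(gt$voxels))
  attr(out, "foreground") <- res$is_fg
  out
}

#' Extract a zero-padded patch (image segment) around a centre
#'
#' Crops a subvolume of the given size centred on a sampled voxel, padding
#' with zeros where the patch extends beyond the grid. Training and
#' validation segments of the wrapped segmenter are typically 25^3 and
#' 17^3 voxels.
#'
#' @param vol [subject_volume()] or 3-D array.
#' @param center length-3 integer voxel index (1-based).
#' @param size patch size per axis; default \code{c(25, 25, 25)}.
#' @return 3-D array of the requested size.
#' @export
extract_patch <- function(vol, center, size = c(25, 25, 25)) {
  arr <- if (inherits(vol, "subject_volume")) vol$voxels else vol
  size <- rep_len(as.integer(size), 3L)
  d <- dim(arr)
  out <- array(0, size)
  lo <- as.integer(center) - (size - 1L) %/% 2L
  hi <- lo + size - 1L
  src_lo <- pmax(lo, 1L); src_hi <- pmin(hi, d)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - lo + 1L; dst_hi <- src_hi - lo + 1L
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Write per-class weight-map manifests
#'
#' Writes each subject's class weight maps as NIfTI files plus one manifest
#' text file per class, one subject path per line, line order coherent
#' between the files — the layout patch-based trainers consume.
#'
#' @param weight_maps list of \code{weight_map} objects.
#' @param dir output directory.
#' @return Invisibly, a named list of the manifest file paths.
#' @export
write_weight_manifests <- function(weight_maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fg = character(0), bg = character(0))
  for (wm in weight_maps) {
    for (cls in c("fg", "bg")) {
      p <- file.path(dir, sprintf("%s_weight_%s.nii", wm$subject_id, cls))
      vol <- subject_volume(wm[[cls]], affine = wm$affine,
                            subject_id = wm$subject_id,
                            channel = paste0("weight_", cls))
      write_volume(vol, p)
      paths[[cls]] <- c(paths[[cls]], p)
    }
  }
  manifests <- list(fg = file.path(dir, "weights_foreground.txt"),
                    bg = file.path(dir, "weights_background.txt"))
  writeLines(paths$fg, manifests$fg)
  writeLines(paths$bg, manifests$bg)
  invisible(manifests)
}
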