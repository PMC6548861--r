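#' Pre-processing configuration
#'
#' Parameters of the per-subject pre-processing pipeline: resample every
#' channel to an isotropic working space coarsened by a global downsampling
#' factor, build an intracranial mask from the TTP channel, and z-normalise
#' each channel within that mask.
#'
#' @param dF global downsampling factor in (0, 1]; default 0.7, the value
#'   needed to fit whole multi-channel heads into segmenter memory.
#' @param target_spacing isotropic target spacing in mm before the factor is
#'   applied; default 1 mm.
#' @param dilation_radius,dilation_iters ball radius (voxels) and iteration
#'   count of the mask-boundary dilation; defaults 1 and 1.
#' @param ttp_threshold intensities strictly above this are treated as
#'   head tissue when binarising TTP; default 0 (skull-stripped background
#'   is exactly zero).
#' @param sd_type \code{"population"} (divide by N, the convention of the
#'   tensor libraries patch-based segmenters build on) or \code{"sample"}.
#' @return A list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(dF = 0.7, target_spacing = c(1, 1, 1),
                              dilation_radius = 1, dilation_iters = 1,
                              ttp_threshold = 0, sd_type = "population") {
  if (length(dF) != 1 || dF <= 0 || dF > 1) {
    stop("dF must be a scalar in (0, 1]", call. = FALSE)
  }
  if (dilation_radius < 0 || dilation_iters < 0) {
    stop("dilation radius and iterations must be >= 0", call. = FALSE)
  }
  sd_type <- match.arg(sd_type, c("population", "sample"))
  structure(list(dF = dF, target_spacing = rep_len(as.double(target_spacing), 3L),
                 dilation_radius = dilation_radius,
                 dilation_iters = dilation_iters,
                 ttp_threshold = ttp_threshold, sd_type = sd_type),
            class = "preprocess_config")
}

#' Intracranial mask from the TTP channel
#'
#' Binarises the TTP map (non-background voxels, see
#' \code{ttp_threshold}) and applies binary dilation to improve the mask
#' boundary. Computed on the native grid; resampling to the working grid
#' happens afterwards with nearest-neighbour interpolation.
#'
#' @param channels named list of [subject_volume()]s containing a TTP entry
#'   (name matched case-insensitively), or a single TTP volume.
#' @param cfg a [preprocess_config()].
#' @return A [binary_mask()] on the native grid.
#' @export
compute_mask <- function(channels, cfg = preprocess_config()) {
  ttp <- find_channel(channels, "TTP")
  if (is.null(ttp)) {
    stop("no TTP channel supplied; the intracranial mask is built from TTP",
         call. = FALSE)
  }
  bin <- array(as.double(abs(ttp$voxels) > cfg$ttp_threshold), dim = dim(ttp))
  if (sum(bin) == 0) {
    stop(sprintf("subject %s: TTP binarisation produced an empty mask",
                 ttp$subject_id), call. = FALSE)
  }
  if (cfg$dilation_radius > 0 && cfg$dilation_iters > 0) {
    bin <- binary_dilate(bin, radius = cfg$dilation_radius,
                         iterations = cfg$dilation_iters)
  }
  binary_mask(bin, affine = ttp$affine, subject_id = ttp$subject_id,
              channel = "intracranial_mask")
}

find_channel <- function(channels, name) {
  if (inherits(channels, "subject_volume")) {
    return(if (toupper(channels$channel) == toupper(name)) channels else NULL)
  }
  labels <- toupper(vapply(channels, function(ch) ch$channel, character(1)))
  nm <- toupper(names(channels) %||% rep("", length(channels)))
  i <- which(labels == toupper(name) | nm == toupper(name))
  if (length(i) == 0) NULL else channels[[i[1]]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-normalise a volume within a mask
#'
#' Sets the in-mask voxels to zero mean and unit variance and everything
#' outside the mask to 0.
#'
#' @param vol a [subject_volume()].
#' @param mask a [binary_mask()] on the same grid.
#' @param sd_type \code{"population"} (default) or \code{"sample"} standard
#'   deviation.
#' @return The normalised [subject_volume()].
#' @export
normalize_in_mask <- function(vol, mask, sd_type = "population") {
  stop_if_grid_mismatch(vol, mask, "volume and mask")
  inside <- mask$voxels > 0
  if (!any(inside)) stop("mask is empty", call. = FALSE)
  vals <- vol$voxels[inside]
  mu <- mean(vals)
  sd_type <- match.arg(sd_type, c("population", "sample"))
  n <- length(vals)
  sdv <- if (sd_type == "population") sqrt(sum((vals - mu)^2) / n)
         else stats::sd(vals)
  if (!is.finite(sdv) || sdv <= 0) {
    stop(sprintf("channel %s has zero in-mask standard deviation",
                 vol$channel), call. = FALSE)
  }
  out <- vol
  arr <- array(0, dim = dim(vol))
  arr[inside] <- (vals - mu) / sdv
  out$voxels <- arr
  out
}

#' Pre-process one subject (resample, mask, normalise)
#'
#' The per-subject pipeline: every channel is resampled to the working grid
#' (\code{target_spacing / dF}); the intracranial mask is computed from the
#' native TTP channel and resampled with nearest-neighbour interpolation;
#' each resampled channel is then z-normalised within the resampled mask,
#' with voxels outside the mask set to 0.
#'
#' @param channels named list of co-registered [subject_volume()]s sharing
#'   one native grid, including a TTP channel.
#' @param cfg a [preprocess_config()].
#' @param verbose log per-channel in-mask mean/SD before normalisation.
#' @return A list with \code{channels} (named list of normalised
#'   working-space volumes, each carrying its forward transform record) and
#'   \code{mask} (the working-space [binary_mask()]).
#' @export
preprocess_subject <- function(channels, cfg = preprocess_config(),
                               verbose = FALSE) {
  if (length(channels) == 0) stop("no channels supplied", call. = FALSE)
  ref <- channels[[1]]
  for (ch in channels) stop_if_grid_mismatch(ref, ch, "subject channels")
  native_mask <- compute_mask(channels, cfg)
  work_mask <- resample_to_spacing(native_mask, cfg$target_spacing, cfg$dF)
  out <- vector("list", length(channels))
  names(out) <- names(channels)
  for (i in seq_along(channels)) {
    res <- resample_to_spacing(channels[[i]], cfg$target_spacing, cfg$dF)
    if (verbose) {
      inside <- work_mask$voxels > 0
      message(sprintf("  %s/%s in-mask mean %.4g sd %.4g",
                      res$subject_id, res$channel,
                      mean(res$voxels[inside]), stats::sd(res$voxels[inside])))
    }
    norm <- normalize_in_mask(res, work_mask, sd_type = cfg$sd_type)
    norm$transform <- res$transform
    out[[i]] <- norm
  }
  list(channels = out, mask = work_mask)
}
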