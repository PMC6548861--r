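#' Single-channel 3-D subject volume
#'
#' The basic container of the toolkit: one channel's voxel grid (e.g. ADC,
#' MTT, rCBF, rCBV or TTP) together with the geometry needed to move between
#' voxel and world (mm) coordinates. World coordinates follow the NIfTI
#' convention: a 0-based voxel index \code{(i,j,k)} maps to
#' \code{affine \%*\% c(i,j,k,1)}.
#'
#' @param voxels 3-D numeric array of intensities.
#' @param affine 4x4 voxel-to-world transform (mm). Defaults to a diagonal
#'   transform built from \code{spacing}.
#' @param spacing per-axis voxel size in mm (length 3). Derived from the
#'   affine's column norms when omitted.
#' @param subject_id subject identifier.
#' @param channel channel label.
#' @param transform optional resampling provenance record (see
#'   [resample_to_spacing()]); kept so restoration to native space is exact
#'   inversion rather than re-estimation.
#'
#' @return An object of class \code{subject_volume}.
#' @seealso [binary_mask()], [probability_map()], [read_volume()]
#' @export
subject_volume <- function(voxels, affine = NULL, spacing = NULL,
                           subject_id = "subject", channel = "unknown",
                           transform = NULL) {
  voxels <- as_grid3d(voxels)
  geom <- resolve_geometry(affine, spacing)
  vol <- structure(
    list(voxels = voxels, affine = geom$affine, spacing = geom$spacing,
         subject_id = subject_id, channel = channel, transform = transform),
    class = "subject_volume")
  validate_subject_volume(vol)
  vol
}

#' 3-D binary mask on a subject's grid
#'
#' Holds ground-truth lesion labels, intracranial masks and binarised
#' predictions. Values are exactly 0 or 1; logical input is accepted.
#'
#' @inheritParams subject_volume
#' @param voxels 3-D array of 0/1 (or logical) values.
#' @return An object of class \code{c("binary_mask", "subject_volume")}.
#' @export
binary_mask <- function(voxels, affine = NULL, spacing = NULL,
                        subject_id = "subject", channel = "mask",
                        transform = NULL) {
  voxels <- as_grid3d(voxels)
  if (is.logical(voxels)) {
    voxels <- array(as.double(voxels), dim = dim(voxels))
  }
  if (!all(voxels %in% c(0, 1))) {
    stop("binary_mask voxels must be exactly 0 or 1", call. = FALSE)
  }
  geom <- resolve_geometry(affine, spacing)
  structure(
    list(voxels = voxels, affine = geom$affine, spacing = geom$spacing,
         subject_id = subject_id, channel = channel, transform = transform),
    class = c("binary_mask", "subject_volume"))
}

#' Two-class voxelwise probability map
#'
#' Per-voxel class probabilities for the two segmentation classes used
#' throughout: foreground (lesion) and background. Probabilities must lie in
#' [0, 1] and sum to one at every voxel (within 1e-5). When only the
#' foreground grid is supplied the background is taken as its complement.
#'
#' @param fg 3-D array of foreground (lesion) probabilities.
#' @param bg 3-D array of background probabilities; default \code{1 - fg}.
#' @inheritParams subject_volume
#' @return An object of class \code{probability_map}.
#' @export
probability_map <- function(fg, bg = NULL, affine = NULL, spacing = NULL,
                            subject_id = "subject", transform = NULL) {
  fg <- as_grid3d(fg)
  if (is.null(bg)) bg <- 1 - fg else bg <- as_grid3d(bg)
  if (!identical(dim(fg), dim(bg))) {
    stop("foreground and background grids must share a shape", call. = FALSE)
  }
  rng <- range(fg, bg)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8) {
    stop("class probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(fg + bg - 1)) > 1e-5) {
    stop("class probabilities must sum to 1 at every voxel (tol 1e-5)",
         call. = FALSE)
  }
  geom <- resolve_geometry(affine, spacing)
  structure(
    list(fg = fg, bg = bg, affine = geom$affine, spacing = geom$spacing,
         subject_id = subject_id, transform = transform),
    class = "probability_map")
}

as_grid3d <- function(x) {
  x <- unclass(x)
  if (is.null(dim(x))) stop("voxels must be a 3-D array", call. = FALSE)
  d <- dim(x)
  if (length(d) > 3) {
    if (all(d[-(1:3)] == 1L)) {
      dim(x) <- d[1:3]
    } else {
      stop("image is not 3-D (extra non-singleton dimensions)", call. = FALSE)
    }
  } else if (length(d) < 3) {
    stop("voxels must be a 3-D array", call. = FALSE)
  }
  storage.mode(x) <- if (is.logical(x)) "logical" else "double"
  attributes(x) <- list(dim = dim(x))
  x
}

resolve_geometry <- function(affine, spacing) {
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    spacing <- rep_len(as.double(spacing), 3L)
    affine <- diag(c(spacing, 1))
  } else {
    affine <- unname(matrix(as.double(affine), 4, 4))
    col_norms <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (is.null(spacing)) spacing <- col_norms
    spacing <- rep_len(as.double(spacing), 3L)
    if (any(abs(spacing - col_norms) > 1e-4 * pmax(spacing, 1))) {
      stop("spacing is inconsistent with the affine's column norms",
           call. = FALSE)
    }
  }
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  list(affine = affine, spacing = spacing)
}

validate_subject_volume <- function(vol) {
  if (anyNA(vol$voxels) || any(!is.finite(vol$voxels))) {
    stop("subject_volume contains undefined values", call. = FALSE)
  }
  invisible(vol)
}

#' @export
dim.subject_volume <- function(x) dim(x$voxels)

#' @export
dim.probability_map <- function(x) dim(x$fg)

#' @export
print.subject_volume <- function(x, ...) {
  cat(sprintf("<subject_volume> %s / %s  %s voxels @ %s mm\n",
              x$subject_id, x$channel,
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  if (!is.null(x$transform)) cat("  resampled (forward transform recorded)\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s / %s  %s voxels, %d foreground\n",
              x$subject_id, x$channel,
              paste(dim(x$voxels), collapse = "x"),
              as.integer(sum(x$voxels))))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s  %s voxels, fg in [%.3f, %.3f]\n",
              x$subject_id, paste(dim(x$fg), collapse = "x"),
              min(x$fg), max(x$fg)))
  invisible(x)
}

# Shared-grid check used by every pairwise voxel operation.
same_grid <- function(a, b, tol = 1e-4) {
  da <- if (inherits(a, "probability_map")) dim(a$fg) else dim(a$voxels)
  db <- if (inherits(b, "probability_map")) dim(b$fg) else dim(b$voxels)
  identical(da, db) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s do not share a voxel grid (shape/affine mismatch)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Lesion volume of a mask in cubic millimetres
#'
#' @param mask a [binary_mask()].
#' @return Foreground voxel count times the voxel volume implied by the
#'   mask's spacing, in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * prod(mask$spacing)
}

# Deterministic sub-seed derivation: one master seed plus a stream name give
# an independent, reproducible stream below 2^31.
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.double(master) * 2654435.0 + h * 97.0) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
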