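#' Offsets of a 3-D ball structuring element
#'
#' A voxel offset belongs to the element iff its Euclidean length (in voxel
#' units) is at most \code{radius}; this is the probe shape used by all
#' morphological operations here, including the radius-3 ball of the
#' hole-filling (FH) post-processing step.
#'
#' @param radius ball radius in voxels (>= 0).
#' @return Integer matrix with one offset (di, dj, dk) per row.
#' @export
ball_element <- function(radius) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  r <- as.integer(ceiling(radius))
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  keep <- sqrt(g$di^2 + g$dj^2 + g$dk^2) <= radius + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# One morphological pass over a 0/1 array. The grid is padded with zeros by
# the element's reach and cropped back, so dilation never wraps around and
# erosion treats outside-the-grid as background.
morph_pass <- function(arr, offsets, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(arr)
  r <- max(abs(offsets), 0L)
  if (r == 0L || nrow(offsets) == 0L) return(arr)
  p <- array(0, d + 2L * r)
  p[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- arr
  acc <- NULL
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    blk <- p[r + o[1] + seq_len(d[1]),
             r + o[2] + seq_len(d[2]),
             r + o[3] + seq_len(d[3])]
    acc <- if (is.null(acc)) blk
           else if (op == "dilate") pmax(acc, blk) else pmin(acc, blk)
  }
  dim(acc) <- d
  acc
}

#' Binary dilation / erosion with a ball structuring element
#'
#' @param mask a [binary_mask()] or plain 0/1 3-D array.
#' @param radius ball radius in voxels.
#' @param iterations number of repeated passes.
#' @return Same type as the input.
#' @export
binary_dilate <- function(mask, radius = 1, iterations = 1) {
  apply_morph(mask, radius, iterations, "dilate")
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius = 1, iterations = 1) {
  apply_morph(mask, radius, iterations, "erode")
}

apply_morph <- function(mask, radius, iterations, op) {
  offsets <- ball_element(radius)
  run <- function(a) {
    for (i in seq_len(iterations)) a <- morph_pass(a, offsets, op)
    a
  }
  if (inherits(mask, "binary_mask")) {
    out <- mask
    out$voxels <- run(mask$voxels)
    out
  } else {
    run(mask)
  }
}

#' Binary closing (the FH hole-filling operation)
#'
#' \code{iterations} dilations with the ball element followed by the same
#' number of erosions. Fills holes in large predicted lesions and bridges
#' reasonably close small components, making binarised predictions more
#' robust. Closing is extensive (the input is a subset of the output) and
#' idempotent at fixed configuration.
#'
#' @param mask a [binary_mask()] or plain 0/1 3-D array.
#' @param radius structuring-element ball radius in voxels (default 3).
#' @param iterations number of dilation passes, matched by the same number
#'   of erosion passes (default 1).
#' @return Same type as the input.
#' @seealso [tune_closing_iterations()] for validation-based selection of
#'   \code{iterations}.
#' @export
binary_close <- function(mask, radius = 3, iterations = 1) {
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  offsets <- ball_element(radius)
  # Work on a halo-padded grid covering the closing's full reach, then crop:
  # this realises the operation on an unbounded background grid, which is
  # what makes extensivity and idempotence exact up to the image border.
  pad <- as.integer(ceiling(radius)) * as.integer(iterations)
  run <- function(a) {
    d <- dim(a)
    big <- array(0, d + 2L * pad)
    big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- a
    for (i in seq_len(iterations)) big <- morph_pass(big, offsets, "dilate")
    for (i in seq_len(iterations)) big <- morph_pass(big, offsets, "erode")
    out <- big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])]
    dim(out) <- d
    out
  }
  if (inherits(mask, "binary_mask")) {
    out <- mask
    out$voxels <- run(mask$voxels)
    out
  } else {
    run(mask)
  }
}
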