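#' Phantom cohort specification
#'
#' Parameters of the synthetic multi-channel stroke phantom: an ellipsoidal
#' intracranial region on a zero background, per-channel tissue intensities
#' and lesion contrasts, Gaussian acquisition noise, spatially smooth
#' in-lesion intensity inhomogeneity, and one lesion drawn from one of the
#' three clinical size/location subtypes (lacunar/subcortical: a small deep
#' sphere; small cortical: small surface-adjacent blobs; big cortical/main
#' artery: a large irregular union of spheres near the cortex). The default
#' category mix mirrors the 10/7/26 subtype composition of a 43-subject
#' acute stroke cohort.
#'
#' @param shape grid shape per axis; default \code{c(48, 48, 48)}.
#' @param spacing voxel size in mm; default 1 mm isotropic.
#' @param category_mix named proportions over the three categories.
#' @param noise_sd SD of additive Gaussian intensity noise; default 4.
#' @param inhomogeneity relative amplitude of the smooth in-lesion
#'   intensity modulation; default 0.15.
#' @param channel_means,channel_contrasts named per-channel tissue
#'   intensity and additive lesion contrast.
#' @param seed master seed; placement, intensity and noise use named
#'   substreams derived from it.
#' @return A list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), spacing = c(1, 1, 1),
                         category_mix = c("lacunar/subcortical" = 10,
                                          "small cortical" = 7,
                                          "big cortical/main artery" = 26),
                         noise_sd = 4, inhomogeneity = 0.15,
                         channel_means = c(ADC = 100, MTT = 80, rCBF = 60,
                                           TTP = 50),
                         channel_contrasts = c(ADC = -35, MTT = 30,
                                               rCBF = -25, TTP = 20),
                         seed = 1) {
  structure(list(shape = as.integer(rep_len(shape, 3L)),
                 spacing = rep_len(as.double(spacing), 3L),
                 category_mix = category_mix / sum(category_mix),
                 noise_sd = noise_sd, inhomogeneity = inhomogeneity,
                 channel_means = channel_means,
                 channel_contrasts = channel_contrasts, seed = seed),
            class = "phantom_spec")
}

phantom_categories <- c("lacunar/subcortical", "small cortical",
                        "big cortical/main artery")

# Euclidean distance (voxels) of every voxel centre to a point.
dist_field <- function(shape, center) {
  i <- seq_len(shape[1]) - center[1]
  j <- seq_len(shape[2]) - center[2]
  k <- seq_len(shape[3]) - center[3]
  sqrt(outer(outer(i^2, j^2, "+"), k^2, "+"))
}

add_sphere <- function(mask, center, radius) {
  mask | (dist_field(dim(mask), center) <= radius)
}

# Normalised radial position of a voxel w.r.t. the head ellipsoid
# (0 = centre, 1 = surface).
head_ellipsoid <- function(shape) {
  c0 <- (shape + 1) / 2
  radii <- shape * 0.42
  i <- (seq_len(shape[1]) - c0[1]) / radii[1]
  j <- (seq_len(shape[2]) - c0[2]) / radii[2]
  k <- (seq_len(shape[3]) - c0[3]) / radii[3]
  sqrt(outer(outer(i^2, j^2, "+"), k^2, "+"))
}

# Smooth random field in [-1, 1]: low-resolution Gaussian grid linearly
# upsampled to the target shape.
smooth_field <- function(shape, coarse = 6L) {
  g <- array(stats::rnorm(coarse^3), dim = rep(coarse, 3))
  for (axis in 1:3) {
    pos <- seq(1, coarse, length.out = shape[axis])
    g <- interp_axis(g, pos, axis, "linear")
  }
  dim(g) <- shape
  g / max(abs(g), 1e-12)
}

place_lesion <- function(shape, category, radial, seed) {
  with_seed(seed, {
    lesion <- array(FALSE, shape)
    ok <- function(center) {
      ci <- pmin(pmax(round(center), 1), shape)
      radial[ci[1], ci[2], ci[3]] < 0.92
    }
    draw_center <- function(lo, hi) {
      # radial band [lo, hi] within the head, rejection-sampled
      for (try in 1:200) {
        c0 <- (shape + 1) / 2
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        r <- stats::runif(1, lo, hi)
        center <- c0 + dir * r * shape * 0.42
        if (ok(center)) return(center)
      }
      stop("could not place lesion inside the head region", call. = FALSE)
    }
    if (category == "lacunar/subcortical") {
      center <- draw_center(0, 0.4)
      lesion <- add_sphere(lesion, center, stats::runif(1, 2, 3.2))
    } else if (category == "small cortical") {
      center <- draw_center(0.6, 0.85)
      n_blob <- sample(1:2, 1)
      for (b in seq_len(n_blob)) {
        off <- stats::rnorm(3, sd = 1.2)
        lesion <- add_sphere(lesion, center + off, stats::runif(1, 1.8, 2.8))
      }
    } else {
      center <- draw_center(0.45, 0.75)
      n_blob <- sample(6:10, 1)
      for (b in seq_len(n_blob)) {
        off <- stats::rnorm(3, sd = 3.5)
        cand <- center + off
        if (!ok(cand)) cand <- center
        lesion <- add_sphere(lesion, cand, stats::runif(1, 3, 5.5))
      }
    }
    lesion
  })
}

#' Generate one multi-channel lesion phantom
#'
#' Builds the synthetic subject the pipeline is exercised on: an
#' ellipsoidal head with zero background, one lesion of the requested
#' category, per-channel lesion contrast, smooth in-lesion intensity
#' inhomogeneity and additive Gaussian noise. The TTP-like channel is
#' strictly positive everywhere inside the head so intracranial-mask
#' construction by TTP binarisation works.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject identifier.
#' @param category lesion category; drawn from \code{spec$category_mix}
#'   when omitted.
#' @param seed overrides \code{spec$seed} for this subject.
#' @return List with \code{channels} (named [subject_volume()]s),
#'   \code{gt} ([binary_mask()]), \code{head} (intracranial
#'   [binary_mask()]), \code{category} and \code{subject_id}.
#' @export
make_phantom <- function(spec = phantom_spec(), subject_id = "phantom",
                         category = NULL, seed = NULL) {
  seed <- seed %||% spec$seed
  shape <- spec$shape
  radial <- head_ellipsoid(shape)
  head <- radial <= 1
  if (is.null(category)) {
    category <- with_seed(derive_seed(seed, paste0("category/", subject_id)),
                          sample(names(spec$category_mix), 1,
                                 prob = spec$category_mix))
  }
  lesion <- place_lesion(shape, category, radial,
                         derive_seed(seed, paste0("placement/", subject_id)))
  lesion <- lesion & head
  if (!any(lesion)) stop("generated lesion is empty", call. = FALSE)
  inhom <- with_seed(derive_seed(seed, paste0("intensity/", subject_id)),
                     smooth_field(shape))
  channels <- vector("list", length(spec$channel_means))
  names(channels) <- names(spec$channel_means)
  for (ci in seq_along(channels)) {
    ch <- names(channels)[ci]
    base <- spec$channel_means[[ch]]
    contrast <- spec$channel_contrasts[[ch]]
    arr <- array(0, shape)
    arr[head] <- base
    arr[lesion] <- base + contrast * (1 + spec$inhomogeneity * inhom[lesion])
    noise <- with_seed(derive_seed(seed, paste("noise", subject_id, ch, sep = "/")),
                       array(stats::rnorm(prod(shape), 0, spec$noise_sd), shape))
    arr[head] <- arr[head] + noise[head]
    if (toupper(ch) == "TTP") {
      arr[head] <- pmax(arr[head], 1)  # mask construction needs TTP > 0
    }
    channels[[ci]] <- subject_volume(arr, spacing = spec$spacing,
                                     subject_id = subject_id, channel = ch)
  }
  list(channels = channels,
       gt = binary_mask(lesion, spacing = spec$spacing,
                        subject_id = subject_id, channel = "GT"),
       head = binary_mask(head, spacing = spec$spacing,
                          subject_id = subject_id, channel = "head"),
       category = category, subject_id = subject_id)
}

#' Degradation specification for synthetic probability maps
#'
#' Controls how a ground-truth mask is turned into an imperfect two-class
#' probability map emulating a trained segmenter's output: interior holes
#' (voxels of the eroded lesion zeroed with some probability — the defect
#' the FH closing step repairs), false-positive blobs, Gaussian blur of the
#' class boundary and additive probability noise.
#'
#' @param blur_fwhm Gaussian blur full width at half maximum, mm.
#' @param noise_sd SD of additive noise on the foreground probability.
#' @param hole_rate probability that an interior lesion voxel is zeroed.
#' @param fp_rate expected number of false-positive blobs per subject.
#' @param seed RNG seed.
#' @return A list of class \code{degradation_spec}.
#' @export
degradation_spec <- function(blur_fwhm = 2, noise_sd = 0.05, hole_rate = 0.3,
                             fp_rate = 1, seed = 1) {
  structure(list(blur_fwhm = blur_fwhm, noise_sd = noise_sd,
                 hole_rate = hole_rate, fp_rate = fp_rate, seed = seed),
            class = "degradation_spec")
}

gauss_blur <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 1e-8) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(arr, perm)
    n <- d[axis]
    pad <- array(0, dim(x) + c(2L * r, 0L, 0L))
    pad[r + seq_len(n), , ] <- x
    acc <- array(0, dim(x))
    for (t in seq_along(k)) {
      acc <- acc + k[t] * pad[(t - 1L) + seq_len(n), , , drop = FALSE]
    }
    arr <- aperm(acc, order(perm))
  }
  arr
}

#' Degrade a ground-truth mask into a noisy probability map
#'
#' \code{prob_fg = clip(blur(gt with holes and false-positive blobs) +
#' noise, 0, 1)}, with the background class as its complement. A
#' zero-degradation spec reproduces the ground truth exactly, giving an
#' oracle segmenter.
#'
#' @param gt ground-truth [binary_mask()].
#' @param spec a [degradation_spec()].
#' @param head optional intracranial [binary_mask()] constraining
#'   false-positive blob placement.
#' @return A [probability_map()] on the ground truth's grid.
#' @export
degrade_gt_to_probs <- function(gt, spec = degradation_spec(), head = NULL) {
  if (sum(gt$voxels) == 0) stop("ground truth is empty", call. = FALSE)
  arr <- gt$voxels
  shape <- dim(arr)
  with_seed(derive_seed(spec$seed, paste0("degrade/", gt$subject_id)), {
    if (spec$hole_rate > 0) {
      interior <- which(binary_erode(arr, radius = 1) > 0)
      if (length(interior) > 0) {
        punch <- interior[stats::runif(length(interior)) < spec$hole_rate]
        arr[punch] <- 0
      }
    }
    if (spec$fp_rate > 0) {
      n_fp <- stats::rpois(1, spec$fp_rate)
      region <- if (is.null(head)) array(TRUE, shape) else head$voxels > 0
      cand <- which(region & gt$voxels == 0)
      for (b in seq_len(n_fp)) {
        if (length(cand) == 0) break
        c_idx <- arrayInd(sample(cand, 1), shape)
        fp <- dist_field(shape, as.double(c_idx)) <= stats::runif(1, 1.5, 3)
        arr[fp & region] <- 1
      }
    }
    if (spec$blur_fwhm > 0) {
      sigma_vox <- spec$blur_fwhm / (2 * sqrt(2 * log(2))) / gt$spacing
      arr <- gauss_blur(arr, sigma_vox)
    }
    if (spec$noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
    }
  })
  fg <- pmin(pmax(arr, 0), 1)
  dim(fg) <- shape
  probability_map(fg, affine = gt$affine, subject_id = gt$subject_id,
                  transform = gt$transform)
}

#' Simulate a phantom cohort
#'
#' Generates \code{n} phantoms with a deterministic category composition
#' following the spec's category mix (largest-remainder apportionment), and
#' per-subject seeds derived from one master seed.
#'
#' @param n number of subjects.
#' @param spec a [phantom_spec()].
#' @param seed master seed; default \code{spec$seed}.
#' @return List of phantoms as returned by [make_phantom()].
#' @export
simulate_cohort <- function(n, spec = phantom_spec(), seed = NULL) {
  seed <- seed %||% spec$seed
  mix <- spec$category_mix
  counts <- floor(mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(mix * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  categories <- rep(names(mix), counts)
  categories <- with_seed(derive_seed(seed, "cohort-order"),
                          sample(categories))
  lapply(seq_len(n), function(i) {
    make_phantom(spec, subject_id = sprintf("phantom%03d", i),
                 category = categories[i],
                 seed = derive_seed(seed, paste0("subject/", i)))
  })
}
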