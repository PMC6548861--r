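test_that("write/read round trip preserves grids, affines and mask binarity", {
  dir <- withr::local_tempdir()
  set.seed(7)
  arr <- array(rnorm(10 * 12 * 14), c(10, 12, 14))
  aff <- diag(c(1.5, 2, 2.5, 1)); aff[1:3, 4] <- c(-10, -20, -5)
  vol <- subject_volume(arr, affine = aff, subject_id = "s1", channel = "ADC")
  p <- file.path(dir, "vol.nii")
  write_volume(vol, p)
  back <- read_volume(p, subject_id = "s1", channel = "ADC")
  expect_equal(back$voxels, arr, tolerance = 1e-6)
  expect_equal(back$affine, aff, tolerance = 1e-5)
  expect_equal(back$spacing, c(1.5, 2, 2.5), tolerance = 1e-5)

  mask <- binary_mask(array(runif(6^3) < 0.4, c(6, 6, 6)), affine = diag(4))
  pm <- file.path(dir, "mask.nii")
  write_volume(mask, pm)
  mback <- read_volume(pm, mask = TRUE)
  expect_identical(mback$voxels, mask$voxels)  # bit-faithful
  expect_true(all(mback$voxels %in% c(0, 1)))
})

test_that("reading squeezes trailing singleton axes and zeroes undefined voxels", {
  dir <- withr::local_tempdir()
  arr4 <- array(rnorm(5 * 5 * 5), c(5, 5, 5, 1))
  p <- file.path(dir, "vol4d.nii")
  RNifti::writeNifti(RNifti::asNifti(arr4), p)
  v <- read_volume(p)
  expect_identical(dim(v), c(5L, 5L, 5L))
  expect_equal(v$voxels, array(arr4, c(5, 5, 5)), tolerance = 1e-6)
  # a genuinely 4-D multi-frame image is rejected
  arr4b <- array(rnorm(5 * 5 * 5 * 2), c(5, 5, 5, 2))
  pb <- file.path(dir, "vol4d2.nii")
  RNifti::writeNifti(RNifti::asNifti(arr4b), pb)
  expect_error(read_volume(pb), "not 3-D")

  arr <- array(1.0, c(4, 4, 4)); arr[1, 1, 1] <- NaN; arr[2, 2, 2] <- Inf
  pn <- file.path(dir, "nan.nii")
  RNifti::writeNifti(RNifti::asNifti(arr), pn)
  expect_warning(v <- read_volume(pn), "undefined")
  expect_equal(v$voxels[1, 1, 1], 0)
  expect_equal(v$voxels[2, 2, 2], 0)
})

test_that("unreadable inputs raise I/O and format errors", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  txt <- withr::local_tempfile(fileext = ".nii")
  writeLines("this is not a nifti", txt)
  expect_error(suppressWarnings(read_volume(txt)), "not a readable NIfTI")
})

test_that("resampling follows the spacing arithmetic and records its transform", {
  v <- subject_volume(array(rnorm(64^3), c(64, 64, 64)), spacing = c(2, 2, 2))
  r <- resample_to_spacing(v, c(1, 1, 1), 1.0)
  expect_identical(dim(r), c(128L, 128L, 128L))
  expect_equal(r$spacing, c(1, 1, 1))

  # 1 mm target with factor 0.7 yields ~1.4286 mm voxels
  r2 <- resample_to_spacing(v, c(1, 1, 1), 0.7)
  expect_equal(r2$spacing, rep(1 / 0.7, 3), tolerance = 1e-12)
  expect_identical(r2$transform$original_dim, c(64L, 64L, 64L))
  expect_equal(r2$transform$original_affine, v$affine)

  expect_error(resample_to_spacing(v, c(-1, 1, 1)), "positive")
  expect_error(resample_to_spacing(v, 1, 0), "scale_factor")
  expect_error(resample_to_spacing(v, 1, 1.2), "scale_factor")
})

test_that("identity resampling and constants are preserved", {
  set.seed(3)
  v <- subject_volume(array(rnorm(12^3), c(12, 12, 12)), spacing = c(1, 1, 1))
  r <- resample_to_spacing(v, c(1, 1, 1), 1.0)
  expect_equal(r$voxels, v$voxels, tolerance = 1e-10)

  konst <- subject_volume(array(5, c(9, 9, 9)), spacing = c(2, 2, 2))
  rk <- resample_to_spacing(konst, c(1, 1, 1), 0.7)
  expect_true(all(abs(rk$voxels - 5) < 1e-10))
})

test_that("restoration inverts the recorded transform onto the native grid", {
  m <- solid_sphere_mask(36, 9)
  mw <- resample_to_spacing(m, c(1, 1, 1), 0.7)
  mr <- restore_to_native(mw, m)
  expect_identical(dim(mr), dim(m))
  expect_equal(mr$affine, m$affine)
  expect_gte(dice_coefficient(m, mr), 0.95)

  zero <- binary_mask(array(0, c(10, 10, 10)))
  zr <- restore_to_native(resample_to_spacing(zero, 1, 0.7), zero)
  expect_equal(sum(zr$voxels), 0)

  pm <- probability_map(array(0.5, c(10, 10, 10)))
  pr <- restore_to_native(resample_to_spacing(pm, 1, 0.7), pm)
  expect_true(all(abs(pr$fg - 0.5) < 1e-9))

  other <- subject_volume(array(0, c(11, 10, 10)))
  expect_error(restore_to_native(mw, other), "does not match")
  expect_error(restore_to_native(m, m), "no forward transform")
})

test_that("transform sidecars survive a write/read round trip", {
  dir <- withr::local_tempdir()
  m <- solid_sphere_mask(24, 6)
  mw <- resample_to_spacing(m, c(1, 1, 1), 0.7)
  p <- file.path(dir, "pred.nii")
  write_volume(mw, p)
  expect_true(file.exists(file.path(dir, "pred.json")))
  back <- read_volume(p, mask = TRUE)
  expect_equal(back$transform$original_dim, dim(m))
  restored <- restore_to_native(back, m)
  expect_identical(dim(restored), dim(m))
})

test_that("probability maps validate their invariants", {
  expect_error(probability_map(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
  expect_error(probability_map(array(0.4, c(2, 2, 2)),
                               bg = array(0.4, c(2, 2, 2))), "sum to 1")
  pm <- probability_map(array(0.3, c(2, 2, 2)))
  expect_equal(pm$bg, array(0.7, c(2, 2, 2)))
})
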