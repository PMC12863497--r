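mk_vol <- function(vals, spacing = c(1, 1, 1)) {
  ct_volume(array(vals, dim = c(length(vals), 1, 1)), spacing = spacing)
}

test_that("window normalization maps the lung window affinely with saturation", {
  v <- mk_vol(c(-600, -1350, 150, 500, 0, -2000))
  u <- window_normalize(v)
  expect_equal(as.numeric(u$voxels[, 1, 1]), c(0.5, 0, 1, 1, 0.9, 0))
  expect_identical(u$domain, "unit")
  expect_error(window_spec(width = 0), class = "habitat_parameter_error")
  expect_error(window_normalize(u), class = "habitat_parameter_error")
})

test_that("window normalization is monotone and idempotent through the window map", {
  set.seed(1)
  hu <- sort(runif(200, -2000, 800))
  u <- window_normalize(mk_vol(hu))$voxels[, 1, 1]
  expect_true(all(diff(u) >= 0))
  # re-express unit values in HU and renormalize: fixed point
  hu2 <- u * 1500 - 1350
  u2 <- window_normalize(mk_vol(hu2))$voxels[, 1, 1]
  expect_equal(as.numeric(u2), as.numeric(u), tolerance = 1e-12)
})

test_that("resampling follows the dimension rounding convention", {
  v <- ct_volume(array(rnorm(10 * 6 * 4), dim = c(10, 6, 4)), spacing = c(2, 2, 2))
  r <- resample_isotropic(v, 1)
  expect_identical(dim(r$voxels), c(20L, 12L, 8L))
  expect_equal(r$spacing, c(1, 1, 1))
  # identity when target equals input spacing
  same <- resample_isotropic(v, 2)
  expect_identical(same$voxels, v$voxels)
  expect_error(resample_isotropic(v, 0), class = "habitat_parameter_error")
})

test_that("mask resampling stays binary and round-trips volume within 10%", {
  nod <- small_nodule(diameter = 14, seed = 3)
  m <- nod$mask
  expect_gte(sum(m$voxels), 100)
  down <- resample_isotropic(m, 2)
  expect_true(is.logical(down$voxels))
  back <- resample_isotropic(down, 1)
  v0 <- sum(m$voxels) * prod(m$spacing)
  v1 <- sum(back$voxels) * prod(back$spacing)
  expect_lt(abs(v1 - v0) / v0, 0.10)
})

test_that("VOI crop is the margin-expanded bounding box clipped to the image", {
  arr <- array(FALSE, dim = c(7, 7, 7)); arr[4, 4, 4] <- TRUE
  vol <- ct_volume(array(rnorm(343), dim = c(7, 7, 7)))
  msk <- lesion_mask(arr)
  cr <- crop_voi(vol, msk, margin_vox = 1L)
  expect_identical(dim(cr$volume$voxels), c(3L, 3L, 3L))
  tight <- crop_voi(vol, msk, margin_vox = 0L)
  expect_identical(dim(tight$volume$voxels), c(1L, 1L, 1L))
  big <- crop_voi(vol, msk, margin_vox = 100L)
  expect_identical(dim(big$volume$voxels), dim(vol$voxels))
  empty <- lesion_mask(array(FALSE, dim = c(7, 7, 7)))
  expect_error(crop_voi(vol, empty), class = "habitat_empty_mask_error")
})

test_that("dice follows the overlap formula and its conventions", {
  a <- array(FALSE, dim = c(4, 4, 1)); b <- a
  a[1:4, 1, 1] <- TRUE                      # |A| = 4
  b[3:4, 1, 1] <- TRUE; b[1:2, 2, 1] <- TRUE  # |B| = 4, overlap 2
  ma <- lesion_mask(a); mb <- lesion_mask(b)
  expect_equal(dice(ma, mb), 0.5)
  expect_equal(dice(ma, ma), 1)
  expect_equal(dice(ma, mb), dice(mb, ma))
  disj <- lesion_mask(array(FALSE, dim = c(4, 4, 1)))
  disj$voxels[1, 4, 1] <- TRUE
  expect_equal(dice(ma, disj), 0)
  e <- lesion_mask(array(FALSE, dim = c(4, 4, 1)))
  expect_equal(dice(e, e), 1)   # documented empty-empty convention
  bad <- lesion_mask(array(FALSE, dim = c(3, 4, 1)))
  expect_error(dice(ma, bad), class = "habitat_alignment_error")
})

test_that("NIfTI round-trip preserves voxels and spacing", {
  nod <- small_nodule(diameter = 10, seed = 9)
  tf <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(nod$volume, tf)
  back <- read_nifti_volume(tf)
  expect_equal(back$voxels, nod$volume$voxels, tolerance = 1e-6)
  expect_equal(back$spacing, nod$volume$spacing)
  tm <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(nod$mask, tm)
  mback <- read_nifti_mask(tm)
  expect_identical(mback$voxels, nod$mask$voxels)
  unlink(c(tf, tm))
})
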