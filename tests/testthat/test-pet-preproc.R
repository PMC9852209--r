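test_that("NIfTI round-trip preserves grid and affine", {
  set.seed(1)
  arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  aff <- diag(c(4, 4, 4, 1)); aff[1:3, 4] <- c(-8, -10, -12)
  v <- brain_volume(arr, aff, "sub01")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  w <- load_volume(f, subject_id = "sub01")
  expect_equal(w$data, arr)
  expect_equal(w$affine, aff)
  expect_identical(w$subject_id, "sub01")
  expect_error(load_volume(f, expected_shape = c(4, 5, 7)), "expected 4x5x7")
})

test_that("degenerate volumes are rejected with informative errors", {
  f4 <- tempfile(fileext = ".nii")
  write_volume(array(1, c(2, 2, 2, 2)), f4)
  expect_error(load_volume(f4), "4-D")
  bad <- array(1, c(3, 3, 3)); bad[1, 1, 1] <- NaN
  expect_error(brain_volume(bad), "1 non-finite voxel")
})

test_that("whole-brain normalization divides by the masked mean", {
  dims <- c(3, 3, 3)
  mask_arr <- array(FALSE, dims); mask_arr[1:4] <- TRUE
  mask <- brain_mask(mask_arr)
  # constant input: all masked voxels become 1
  v <- brain_volume(array(7, dims))
  out <- normalize_whole_brain(v, mask)
  expect_equal(unique(out$data[mask_arr]), 1)
  expect_true(all(out$data[!mask_arr] == 0))
  # hand-derived: masked values 1..4, mean 2.5
  arr <- array(9, dims); arr[1:4] <- 1:4
  out2 <- normalize_whole_brain(brain_volume(arr), mask)
  expect_equal(out2$data[1:4], c(0.4, 0.8, 1.2, 1.6))
  expect_lt(abs(mean(out2$data[mask_arr]) - 1), 1e-10)
  expect_error(normalize_whole_brain(brain_volume(array(0, dims)), mask),
               "positive")
})

test_that("gaussian smoothing: identity limits and constant invariance", {
  set.seed(2)
  arr <- array(runif(5^3), c(5, 5, 5))
  v <- brain_volume(arr, diag(c(4, 4, 4, 1)))
  expect_identical(gaussian_smooth(v, 1)$data, arr)  # below half a voxel
  const <- brain_volume(array(3.5, c(6, 6, 6)), diag(c(2, 2, 2, 1)))
  expect_equal(gaussian_smooth(const, 10)$data, const$data, tolerance = 1e-12)
})

test_that("gaussian smoothing matches dense convolution away from edges", {
  dims <- c(18, 18, 18)
  set.seed(3)
  arr <- array(0, dims)
  arr[8:10, 8:10, 8:10] <- runif(27)       # support > 6 sigma from edges
  vox <- c(4, 4, 4)
  sigma <- 10 / (2 * sqrt(2 * log(2))) / vox
  v <- brain_volume(arr, diag(c(vox, 1)))
  got <- gaussian_smooth(v, 10)$data
  want <- dense_smooth_oracle(arr, sigma)
  # voxels whose kernel window is unclipped agree to rounding error;
  # clipped rows differ only by the renormalized sub-3e-4 kernel tail
  rad <- ceiling(6 * max(sigma))
  inner <- (rad + 1):(18 - rad)
  expect_lt(max(abs(got[inner, inner, inner] - want[inner, inner, inner])), 1e-12)
  expect_lt(max(abs(got - want)), 1e-7)
  # total intensity conserved
  expect_lt(abs(sum(got) - sum(arr)) / sum(arr), 1e-6)
})

test_that("feature assembly is a bijection onto the masked voxels", {
  dims <- c(4, 4, 3)
  mask_arr <- array(FALSE, dims)
  mask_arr[c(1, 5, 9, 20, 33)] <- TRUE
  mask <- brain_mask(mask_arr)
  set.seed(4)
  vols <- lapply(1:2, function(i)
    brain_volume(array(rnorm(prod(dims)), dims), subject_id = paste0("s", i)))
  fm <- assemble_features(vols, mask)
  expect_equal(dim(fm$values), c(2L, 5L))
  expect_identical(fm$subject_ids, c("s1", "s2"))
  # scatter reproduces the masked volume exactly
  back <- scatter_feature_row(fm, "s2")
  expect_equal(back[mask_arr], vols[[2]]$data[mask_arr])
  expect_true(all(back[!mask_arr] == 0))
  # voxel_index maps columns onto 0-based coordinates of masked voxels
  expect_identical(fm$voxel_index, arrayInd(which(mask_arr), dims) - 1L)
  # column order is a pure function of the mask
  fm2 <- assemble_features(rev(vols), mask)
  expect_identical(fm2$lin_index, fm$lin_index)
  # shape mismatches name the offending subject
  bad <- brain_volume(array(1, c(3, 3, 3)), subject_id = "odd")
  expect_error(assemble_features(list(vols[[1]], bad), mask), "odd")
})

test_that("normalization commutes with assembly", {
  dims <- c(5, 5, 5)
  mask <- brain_mask(array(rep(c(TRUE, FALSE), length.out = prod(dims)), dims))
  set.seed(5)
  vols <- lapply(1:3, function(i)
    brain_volume(array(runif(prod(dims), 1, 2), dims), subject_id = paste0("s", i)))
  a <- assemble_features(lapply(vols, normalize_whole_brain, mask = mask), mask)
  b <- assemble_features(vols, mask)
  b$values <- b$values / rowMeans(b$values)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})
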