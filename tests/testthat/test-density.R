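test_that("fixed-threshold binarization is a strict intensity cut", {
  vox <- array(0, c(4, 4, 4))
  vox[1:2, , ] <- 255
  vol <- volume_image(vox, c(1, 1, 1), "EC")
  b <- binarize_volume(vol, "fixed", fixed_threshold = 128)
  expect_identical(b$mask, vox == 255)
  expect_identical(b$threshold, 128)
  expect_true(all(!binarize_volume(
    volume_image(array(0, c(3, 3, 3)), c(1, 1, 1), "EC"),
    "fixed", fixed_threshold = 1)$mask))
  expect_error(binarize_volume(vol, "fixed"), "fixed_threshold")
})

test_that("otsu matches an exhaustive intra-class-variance sweep on a bimodal volume", {
  set.seed(1)
  vox <- array(0, c(10, 10, 10))
  vox[] <- sample(c(30, 200), 1000, replace = TRUE, prob = c(0.8, 0.2))
  vox <- vox + array(sample(-5:5, 1000, TRUE), dim(vox))
  vol <- volume_image(vox, c(1, 1, 1), "EC")
  b <- binarize_volume(vol, "otsu")
  # oracle: sweep every integer threshold, minimize weighted intra-class var
  vals <- as.vector(vox)
  wvar <- vapply(0:254, function(t) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) return(Inf)
    (length(lo) * stats::var(lo) * (length(lo) - 1) / length(lo) +
       length(hi) * stats::var(hi) * (length(hi) - 1) / length(hi))
  }, numeric(1))
  t_star <- which.min(wvar) - 1
  # any threshold between the modes yields the same mask; compare masks
  expect_identical(b$mask, vox > t_star)
  expect_gt(b$threshold, 35)
  expect_lt(b$threshold, 195)
})

test_that("otsu on a constant volume is an explicit error", {
  vol <- volume_image(array(42, c(4, 4, 4)), c(1, 1, 1), "EC")
  expect_error(binarize_volume(vol, "otsu"), "constant")
})

test_that("density fraction and physical volume are exact bookkeeping", {
  mask <- array(FALSE, c(5, 5, 5))
  roi <- array(TRUE, c(5, 5, 5))
  expect_equal(vessel_density(mask, roi, c(2, 2, 2))$density_fraction, 0)
  mask2 <- roi
  d <- vessel_density(mask2, roi, c(2, 2, 2))
  expect_equal(d$density_fraction, 1)
  expect_equal(d$physical_volume, 125 * 8)
  mask3 <- array(FALSE, c(5, 5, 5)); mask3[1:2, 1, 1] <- TRUE
  d3 <- vessel_density(mask3, NULL, c(1, 2, 3))
  expect_equal(d3$density_fraction, 2 / 125)
  expect_equal(d3$physical_volume, 2 * 6)
  expect_error(vessel_density(mask3, array(FALSE, c(5, 5, 5)), c(1, 1, 1)),
               "empty region")
  expect_error(vessel_density(mask3, array(TRUE, c(4, 5, 5)), c(1, 1, 1)),
               "same shape")
})

test_that("cylinder phantom density recovers the analytic volume within 10%", {
  fx <- tube_fixture(length_um = 200, radius_um = 10,
                     shape = c(100L, 100L, 104L), spacing = c(2, 2, 2))
  vol <- rasterize_tree(fx$tree, fx$params, "EC")
  b <- binarize_volume(vol, "fixed", fixed_threshold = 100)
  d <- vessel_density(b, NULL, fx$params$spacing)
  expect_lt(abs(d$physical_volume - pi * 10^2 * 200) / (pi * 10^2 * 200),
            0.10)
})

test_that("adding a disjoint vessel never decreases the density fraction", {
  base <- quiet_mask(0)
  more <- quiet_mask(10)
  sp <- base$params$spacing
  d0 <- vessel_density(base$mask, NULL, sp)$density_fraction
  d1 <- vessel_density(base$mask | more$mask, NULL, sp)$density_fraction
  expect_gte(d1, d0)
  expect_gte(d0, 0); expect_lte(d1, 1)
})

test_that("density fraction is non-decreasing across presets by sprout burden", {
  fracs <- vapply(c("normoxia", "suhx", "hx"), function(pre) {
    p <- preset_params(pre, seed = 1, background_level = 0,
                       shot_noise_scale = 0, gaussian_noise_sd = 0)
    vol <- rasterize_tree(generate_vessel_tree(p), p, "EC")
    b <- binarize_volume(vol, "fixed", fixed_threshold = 100)
    vessel_density(b, NULL, p$spacing)$density_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})
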