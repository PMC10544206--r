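test_that("generator is bit-identical under identical seed and differs across seeds", {
  p <- synth_params(seed = 11, n_sprouts = 6)
  t1 <- generate_vessel_tree(p)
  t2 <- generate_vessel_tree(p)
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$edges, t2$edges)
  expect_identical(t1$polylines, t2$polylines)
  v1 <- rasterize_tree(t1, p, "EC")
  v2 <- rasterize_tree(t2, p, "EC")
  expect_identical(v1$voxels, v2$voxels)
  t3 <- generate_vessel_tree(synth_params(seed = 12, n_sprouts = 6))
  expect_false(identical(t1$nodes, t3$nodes))
})

test_that("neovessel ground-truth totals are exact sums of edge lengths", {
  expect_identical(
    generate_vessel_tree(synth_params(n_sprouts = 0))$metadata$total_neovessel_length,
    0)
  tr <- generate_vessel_tree(synth_params(
    seed = 5, n_sprouts = 20, sprout_length_mean = 100, sprout_length_sd = 0))
  expect_equal(tr$metadata$total_neovessel_length, 2000, tolerance = 1e-9)
  # independent re-summation over emitted coordinates (seed 42 defaults)
  tr42 <- generate_vessel_tree(synth_params(seed = 42, n_sprouts = 8))
  resum <- sum(vapply(seq_len(nrow(tr42$edges)), function(i) {
    pl <- tr42$polylines[[i]]
    if (is.null(pl)) {
      a <- unlist(tr42$nodes[match(tr42$edges$from[i], tr42$nodes$id),
                             c("z", "y", "x")])
      b <- unlist(tr42$nodes[match(tr42$edges$to[i], tr42$nodes$id),
                             c("z", "y", "x")])
      pl <- rbind(a, b)
    }
    sum(sqrt(rowSums((pl[-1, , drop = FALSE] -
                        pl[-nrow(pl), , drop = FALSE])^2)))
  }, numeric(1)))
  expect_equal(sum(tr42$edges$length), resum, tolerance = 1e-9)
  expect_equal(tr42$metadata$total_baseline_length +
                 tr42$metadata$total_neovessel_length,
               resum, tolerance = 1e-9)
})

test_that("tree respects geometry invariants (taper, boundary, hilum)", {
  p <- synth_params(seed = 9, n_sprouts = 10, elongation_factor = 1.3)
  tr <- generate_vessel_tree(p)
  b <- tr$metadata$lung_boundary
  # radii non-increasing from parent to child along every edge
  for (i in seq_len(nrow(tr$edges))) {
    rf <- tr$nodes$radius[match(tr$edges$from[i], tr$nodes$id)]
    rt <- tr$nodes$radius[match(tr$edges$to[i], tr$nodes$id)]
    expect_lte(rt, rf + 1e-9)
  }
  # all nodes inside the boundary ellipsoid
  fr <- vapply(seq_len(nrow(tr$nodes)), function(i) {
    pulmovasc:::ellipsoid_frac(unlist(tr$nodes[i, c("z", "y", "x")]), b)
  }, numeric(1))
  expect_true(all(fr <= 1 + 1e-9))
  # hilum on the surface
  expect_equal(pulmovasc:::ellipsoid_frac(tr$metadata$hilum, b), 1,
               tolerance = 1e-6)
})

test_that("excessive elongation is an error naming tips, not a silent clip", {
  expect_error(generate_vessel_tree(synth_params(elongation_factor = 1.7)),
               "boundary")
})

test_that("rasterized straight tube matches the analytic cylinder volume", {
  fx <- tube_fixture(length_um = 200, radius_um = 4)
  vol <- rasterize_tree(fx$tree, fx$params, "EC")
  count <- sum(vol$voxels > 0)
  voxvol <- prod(fx$params$spacing)
  h <- sqrt(sum(fx$params$spacing^2)) / 2 # half voxel diagonal
  lo <- pi * (fx$radius - h)^2 * fx$length / voxvol
  hi <- pi * (fx$radius + h)^2 * (fx$length + 2 * h) / voxvol
  expect_gte(count, lo)
  expect_lte(count, hi)
})

test_that("empty tree with zero background rasterizes to an all-zero volume", {
  nodes <- data.frame(id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), radius = numeric())
  edges <- data.frame(from = integer(), to = integer(), label = character(),
                      length = numeric(), radius = numeric())
  empty <- vessel_tree(nodes, edges)
  p <- quiet_params(volume_shape = c(16L, 16L, 16L), spacing = c(2, 2, 2))
  expect_true(all(rasterize_tree(empty, p, "EC")$voxels == 0))
})

test_that("physical foreground volume is resolution independent within 10%", {
  fx <- tube_fixture(length_um = 150, radius_um = 6,
                     shape = c(40L, 60L, 160L), spacing = c(2.2, 1.13, 1.13))
  v1 <- rasterize_tree(fx$tree, fx$params, "EC")
  p2 <- quiet_params(volume_shape = c(14L, 30L, 80L),
                     spacing = c(6.6, 2.27, 2.27))
  v2 <- rasterize_tree(fx$tree, p2, "EC")
  pv1 <- sum(v1$voxels > 0) * prod(v1$spacing)
  pv2 <- sum(v2$voxels > 0) * prod(v2$spacing)
  expect_lt(abs(pv1 - pv2) / pv1, 0.10)
})

test_that("SMA channel paints an annular wall on baseline edges only", {
  p <- quiet_params(seed = 21, n_sprouts = 12)
  tr <- generate_vessel_tree(p)
  sma <- rasterize_tree(tr, p, "SMA")
  ec <- rasterize_tree(tr, p, "EC")
  # wall exists, and the lumen interior is dark in the SMA channel
  expect_gt(sum(sma$voxels > 0), 0)
  root <- unlist(tr$nodes[1, c("z", "y", "x")])
  # voxel at the root centerline: inside EC lumen, outside SMA wall
  iv <- pmax(1, round(root / p$spacing + 0.5))
  expect_gt(ec$voxels[iv[1], iv[2], iv[3]], 0)
  expect_equal(sma$voxels[iv[1], iv[2], iv[3]], 0)
  # neovessel sprout tips are unmuscularized: no SMA signal at tip
  tips <- tr$edges$to[tr$edges$label == "neovessel"]
  for (id in tips[1:3]) {
    tp <- unlist(tr$nodes[match(id, tr$nodes$id), c("z", "y", "x")])
    it <- pmax(1, pmin(p$volume_shape, round(tp / p$spacing + 0.5)))
    expect_equal(sma$voxels[it[1], it[2], it[3]], 0)
  }
})

test_that("maximum-intensity projection behaves like a per-pixel maximum", {
  vox <- array(7, c(4, 5, 6))
  vol <- volume_image(vox, c(1, 1, 1), "EC")
  pr <- render_projection(vol, "z", "mip")
  expect_true(all(pr$pixels == pr$pixels[1, 1])) # constant stays constant
  vox2 <- array(0, c(4, 5, 6))
  vox2[2, 3, 4] <- 200
  pr2 <- render_projection(volume_image(vox2, c(1, 1, 1), "EC"))
  expect_equal(sum(pr2$pixels > 0), 1)
  expect_equal(unname(which(pr2$pixels > 0, arr.ind = TRUE)[1, ]), c(3, 4))
  # projection foreground dominates any single slice
  f <- quiet_mask(5)
  vol3 <- rasterize_tree(f$tree, f$params, "EC")
  pr3 <- render_projection(vol3)
  slice_fg <- max(apply(vol3$voxels > 0, 1, sum))
  expect_gte(sum(pr3$pixels > 0), slice_fg)
  expect_error(render_projection(vol3, axis = "w"))
})

test_that("projection perturbation is graded, nested and deterministic", {
  pr <- small_projection()
  expect_identical(perturb_projection(pr, 0, seed = 4)$pixels, pr$pixels)
  a <- perturb_projection(pr, 3, seed = 4)
  b <- perturb_projection(pr, 3, seed = 4)
  expect_identical(a$pixels, b$pixels)
  mad <- vapply(1:5, function(lev) {
    mean(abs(perturb_projection(pr, lev, seed = 4)$pixels - pr$pixels))
  }, numeric(1))
  expect_true(all(diff(mad) > 0))
})

test_that("group-table simulation is reproducible and degenerate at sd 0", {
  t1 <- simulate_group_table(c(1, 2, 3), c(0, 0, 0), 5, seed = 2)
  expect_identical(t1$value, rep(c(1, 2, 3), each = 5))
  t2 <- simulate_group_table(c(1, 2), c(0.5, 0.5), 7, seed = 9)
  t3 <- simulate_group_table(c(1, 2), c(0.5, 0.5), 7, seed = 9)
  expect_identical(t2, t3)
  expect_error(simulate_group_table(c(1, 2), c(-1, 1), 5), ">= 0")
  expect_error(simulate_group_table(c(1, 2), c(1, 1), 1), ">= 2")
  expect_error(simulate_group_table(c(1, 2), c(1, 1, 1), 5), "equal length")
})

test_that("presets order the sprout burden Nx < SuHx < Hx", {
  pn <- preset_params("normoxia")
  ps <- preset_params("suhx")
  ph <- preset_params("hx")
  expect_lt(pn$n_sprouts, ps$n_sprouts)
  expect_lt(ps$n_sprouts, ph$n_sprouts)
  expect_lte(pn$elongation_factor, ps$elongation_factor)
  expect_lt(ps$elongation_factor, ph$elongation_factor)
  expect_identical(voxel_geometry("x5"), c(13.2, 4.54, 4.54))
  expect_identical(voxel_geometry("x10"), c(6.6, 2.27, 2.27))
  expect_identical(voxel_geometry("x20"), c(2.2, 1.13, 1.13))
})
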