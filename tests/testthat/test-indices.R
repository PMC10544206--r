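test_that("angiogenesis index is the exact, scale-invariant ratio", {
  expect_equal(angiogenesis_index(0, 5000), 0)
  expect_equal(angiogenesis_index(1000, 5000), 0.2)
  s <- 3.7
  expect_equal(angiogenesis_index(1000 * s, 5000 * s),
               angiogenesis_index(1000, 5000))
  expect_error(angiogenesis_index(100, 0), "> 0")
  expect_error(angiogenesis_index(100, -5), "> 0")
  expect_error(angiogenesis_index(-1, 100), ">= 0")
})

test_that("lung circumference matches analytic perimeters within 2%", {
  px <- 2
  n <- 600
  # circle radius 500 um
  R <- matrix(rep(seq_len(n), n), n)
  C <- matrix(rep(seq_len(n), each = n), n)
  ctr <- (n + 1) / 2
  circ_mask <- ((R - ctr)^2 + (C - ctr)^2) * px^2 <= 500^2
  got <- measure_lung_circumference(circ_mask, pixel_size = px)
  expect_lt(abs(got - 2 * pi * 500) / (2 * pi * 500), 0.02)
  # square side 100 um
  sq <- matrix(FALSE, 120, 120)
  sq[11:60, 21:70] <- TRUE
  got_sq <- measure_lung_circumference(sq, pixel_size = 2)
  expect_lt(abs(got_sq - 400) / 400, 0.02)
  # ellipse 300 x 500 um semi-axes vs arc-length quadrature oracle
  ell_mask <- ((R - ctr)^2 / (300 / px)^2 + (C - ctr)^2 / (500 / px)^2) <= 1
  got_ell <- measure_lung_circumference(ell_mask, pixel_size = px)
  th <- seq(0, 2 * pi, length.out = 100001)
  f <- sqrt((300 * sin(th))^2 + (500 * cos(th))^2)
  oracle <- sum((f[-1] + f[-length(f)]) / 2) * diff(th[1:2])
  expect_lt(abs(got_ell - oracle) / oracle, 0.02)
  # analytic boundary descriptor agrees with its own mid-axial ellipse
  b <- lung_boundary(c(0, 0, 0), c(100, 300, 500), c(0, 0, -500))
  expect_lt(abs(measure_lung_circumference(b) - oracle) / oracle, 1e-4)
  expect_error(measure_lung_circumference(matrix(FALSE, 5, 5), 1),
               "degenerate")
})

test_that("elongation index spans its limiting cases", {
  b <- lung_boundary(c(50, 50, 50), c(40, 40, 40), c(50, 50, 10))
  # all termini at the hilum
  nodes <- data.frame(id = 1:2, z = 50, y = 50, x = c(10, 10.5), radius = 1)
  edges <- data.frame(from = 1L, to = 2L, label = "baseline",
                      length = 0.5, radius = 1)
  tr <- vessel_tree(nodes, edges, metadata = list(
    hilum = c(50, 50, 10), lung_boundary = b))
  expect_lt(elongation_index(tr), 0.02)
  # one straight branch from hilum to the antipodal boundary point
  nodes2 <- data.frame(id = 1:2, z = 50, y = 50, x = c(10, 90), radius = 1)
  edges2 <- data.frame(from = 1L, to = 2L, label = "baseline",
                       length = 80, radius = 1)
  tr2 <- vessel_tree(nodes2, edges2, metadata = list(
    hilum = c(50, 50, 10), lung_boundary = b))
  expect_equal(elongation_index(tr2), 1, tolerance = 1e-6)
  expect_error(elongation_index(tr2, hilum = c(50, 50, 500)), "outside")
})

test_that("elongation index increases with the generator elongation factor", {
  idx <- vapply(c(1, 1.5), function(f) {
    p <- quiet_params(seed = 13, elongation_factor = f)
    elongation_index(generate_vessel_tree(p))
  }, numeric(1))
  expect_gt(idx[2], idx[1])
})

test_that("elongation index read from a rasterized SMA skeleton preserves the ordering", {
  idx <- vapply(c(1, 1.4), function(f) {
    p <- quiet_params(seed = 13, elongation_factor = f)
    tr <- generate_vessel_tree(p)
    # SMA stains an annular wall: close with a radius larger than the
    # lumen so the shell becomes a solid tube before centerline extraction
    sk <- skeletonize_mask(
      rasterize_tree(tr, p, "SMA")$voxels > 100, p$spacing,
      close_radius = 8)
    elongation_index(sk, tr$metadata$hilum, tr$metadata$lung_boundary)
  }, numeric(1))
  expect_gt(idx[2], idx[1])
})

test_that("one-call angiogenesis pipeline reproduces its parts", {
  f0 <- quiet_mask(0)
  f10 <- quiet_mask(10)
  post_vol <- rasterize_tree(f10$tree, f10$params, "EC")
  base_vol <- rasterize_tree(f0$tree, f0$params, "EC")
  res <- measure_angiogenesis(post_vol, base_vol,
                              f10$tree$metadata$lung_boundary,
                              method = "fixed", fixed_threshold = 100)
  expect_s3_class(res, "index_result")
  expect_equal(res$angiogenesis_index,
               res$total_neovessel_length / res$lung_circumference)
  expect_gt(res$angiogenesis_index, 0)
})
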