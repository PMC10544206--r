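test_that("preprocessing is identity on conforming input and area-exact otherwise", {
  cfg <- similarity_config()
  m <- matrix(runif(256 * 256, 0, 255), 256, 256)
  expect_equal(preprocess_image(m, cfg), m)
  rgb <- array(60, c(64, 64, 3))
  g <- preprocess_image(rgb, similarity_config(target_size = 64))
  expect_true(all(abs(g - 60) < 1e-9))
  # 512^2 checkerboard downsampled by 2: exact block means
  cb <- matrix(0, 512, 512)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 255
  small <- preprocess_image(cb, cfg)
  expect_lt(abs(mean(small) - mean(cb)), 1)
  expect_true(all(abs(small - 127.5) < 1e-9))
  expect_error(preprocess_image(matrix(numeric(0), 0, 0), cfg), "non-empty")
})

test_that("detector finds nothing in flat images and localizes a blob", {
  cfg <- similarity_config()
  flat <- matrix(128, 256, 256)
  expect_equal(nrow(detect_and_describe(flat, cfg)$keypoints), 0)
  # single Gaussian blob at (120, 90) in (row, col)
  R <- matrix(rep(1:256, 256), 256)
  C <- matrix(rep(1:256, each = 256), 256)
  blob <- 220 * exp(-((R - 120)^2 + (C - 90)^2) / (2 * 3^2))
  kp <- detect_and_describe(blob, cfg)
  expect_gt(nrow(kp$keypoints), 0)
  d <- sqrt((kp$keypoints$y - 120)^2 + (kp$keypoints$x - 90)^2)
  expect_lte(min(d), 3)
  # determinism
  kp2 <- detect_and_describe(blob, cfg)
  expect_identical(kp$keypoints, kp2$keypoints)
  expect_identical(kp$descriptors, kp2$descriptors)
})

test_that("matcher distances are Hamming and self-matching scores zero", {
  cfg <- similarity_config()
  pr <- small_projection()
  kp <- detect_and_describe(pr, cfg)
  expect_gt(nrow(kp$keypoints), 0)
  self <- match_features(kp, kp, cfg)
  expect_equal(self$similarity_score, 0)
  expect_equal(self$n_matches, nrow(kp$keypoints))
  # two single-descriptor sets: distance is the popcount of the XOR
  set.seed(7)
  mk1 <- function(bits) {
    structure(list(
      keypoints = data.frame(x = 1, y = 1, scale = 1, orientation = 0,
                             response = 1),
      descriptors = matrix(bits, 1)), class = "keypoint_set")
  }
  a_bits <- sample(c(TRUE, FALSE), 486, TRUE)
  b_bits <- sample(c(TRUE, FALSE), 486, TRUE)
  m <- match_features(mk1(a_bits), mk1(b_bits), cfg)
  expect_equal(m$n_matches, 1)
  expect_equal(m$similarity_score, sum(xor(a_bits, b_bits)))
  expect_error(
    match_features(mk1(a_bits),
                   structure(list(keypoints = mk1(b_bits)$keypoints,
                                  descriptors = matrix(b_bits[1:100], 1)),
                             class = "keypoint_set"), cfg),
    "descriptor lengths")
})

test_that("mutual-NN matching equals the exhaustive pairwise oracle", {
  cfg <- similarity_config()
  for (seed in 1:5) {
    set.seed(seed)
    na <- sample(3:40, 1); nb <- sample(3:40, 1)
    A <- matrix(sample(c(TRUE, FALSE), na * 486, TRUE), na)
    B <- matrix(sample(c(TRUE, FALSE), nb * 486, TRUE), nb)
    ksa <- structure(list(
      keypoints = data.frame(x = seq_len(na), y = 1, scale = 1,
                             orientation = 0, response = 1),
      descriptors = A), class = "keypoint_set")
    ksb <- structure(list(
      keypoints = data.frame(x = seq_len(nb), y = 1, scale = 1,
                             orientation = 0, response = 1),
      descriptors = B), class = "keypoint_set")
    got <- match_features(ksa, ksb, cfg)
    # oracle: full O(n^2) double loop with first-index tie break
    D <- matrix(0L, na, nb)
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      D[i, j] <- sum(xor(A[i, ], B[j, ]))
    }
    pairs <- list()
    for (i in seq_len(na)) {
      j <- which.min(D[i, ])
      if (which.min(D[, j]) == i) pairs[[length(pairs) + 1L]] <-
          c(i, j, D[i, j])
    }
    oracle <- do.call(rbind, pairs)
    expect_equal(nrow(got$pairs), nrow(oracle))
    expect_equal(got$pairs$index_a, oracle[, 1])
    expect_equal(got$pairs$index_b, oracle[, 2])
    expect_equal(got$pairs$distance, oracle[, 3])
  }
})

test_that("empty keypoint sets flag an undefined score rather than zero", {
  cfg <- similarity_config()
  flat <- matrix(0, 256, 256)
  res <- similarity_score(flat, flat, cfg)
  expect_true(res$flag_undefined)
  expect_true(is.na(res$similarity_score))
  expect_equal(res$n_matches, 0)
})

test_that("similarity score is symmetric and zero on identical renders", {
  cfg <- similarity_config()
  pa <- small_projection(seed = 3)
  pb <- perturb_projection(pa, 3, seed = 8)
  expect_equal(similarity_score(pa, pa, cfg)$similarity_score, 0)
  ab <- similarity_score(pa, pb, cfg)
  ba <- similarity_score(pb, pa, cfg)
  expect_equal(ab$similarity_score, ba$similarity_score)
  expect_equal(ab$n_matches, ba$n_matches)
  expect_gt(ab$similarity_score, 0)
})

test_that("spatial score mode reports pixel displacement instead of bits", {
  cfg_d <- similarity_config()
  cfg_s <- similarity_config(score_space = "spatial")
  pa <- small_projection(seed = 3)
  self_sp <- similarity_score(pa, pa, cfg_s)
  expect_equal(self_sp$similarity_score, 0)
  pb <- perturb_projection(pa, 2, seed = 8)
  d_desc <- similarity_score(pa, pb, cfg_d)$similarity_score
  d_sp <- similarity_score(pa, pb, cfg_s)$similarity_score
  expect_gt(d_sp, 0)
  expect_false(isTRUE(all.equal(d_desc, d_sp)))
})

test_that("ratio matcher keeps one-to-one pairs and respects the ratio", {
  cfg <- similarity_config(matcher = "bruteforce-ratio", ratio = 0.9)
  pr <- small_projection()
  kp <- detect_and_describe(pr, similarity_config())
  m <- match_features(kp, kp, cfg)
  expect_lte(max(table(m$pairs$index_b)), 1)
  expect_equal(m$similarity_score, 0) # self NN at distance 0 passes ratio
})
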