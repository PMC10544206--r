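#' Configuration for the 2.5D image-similarity pipeline
#'
#' Fixed, versioned detector/descriptor/matcher settings so that similarity
#' scores are comparable across images and runs — cross-image comparability
#' is the whole point of the analysis.
#'
#' The detector builds a nonlinear-diffusion (Perona-Malik) scale space,
#' finds scale-space extrema of the scale-normalized determinant-of-Hessian
#' response, and describes each keypoint with an upright binary descriptor
#' of pairwise intensity/derivative comparisons over nested grids, matched
#' by Hamming distance.
#'
#' @param target_size side of the square working image (default 256 px).
#' @param detector_threshold response cutoff for scale-space extrema.
#' @param n_octaves number of scale octaves (3 sublevels each).
#' @param descriptor_bits descriptor length; at most 486 (the full nested
#'   2x2 + 3x3 + 4x4 comparison set over 3 channels).
#' @param matcher `"bruteforce-symmetric"` (mutual nearest neighbor,
#'   parameter-free and symmetric — the default) or `"bruteforce-ratio"`
#'   (Lowe ratio test).
#' @param ratio ratio-test threshold in (0, 1], used by the ratio matcher.
#' @param grayscale_weights RGB collapse weights, must sum to 1 (default
#'   ITU-R BT.601 luma).
#' @param max_keypoints keep at most this many strongest keypoints.
#' @param score_space `"descriptor"`: similarity score is the mean Hamming
#'   distance over accepted matches (the standard reading of "match
#'   distance"); `"spatial"`: mean image-space displacement of matched
#'   keypoints instead.
#' @return list of class `similarity_config`.
#' @export
similarity_config <- function(target_size = 256L,
                              detector_threshold = 1e-5,
                              n_octaves = 3L,
                              descriptor_bits = 486L,
                              matcher = c("bruteforce-symmetric",
                                          "bruteforce-ratio"),
                              ratio = 0.8,
                              grayscale_weights = c(0.299, 0.587, 0.114),
                              max_keypoints = 400L,
                              score_space = c("descriptor", "spatial")) {
  matcher <- match.arg(matcher)
  score_space <- match.arg(score_space)
  stopifnot(target_size > 0, ratio > 0, ratio <= 1,
            abs(sum(grayscale_weights) - 1) < 1e-8,
            descriptor_bits >= 1, descriptor_bits <= 486)
  structure(list(target_size = as.integer(target_size),
                 detector_threshold = detector_threshold,
                 n_octaves = as.integer(n_octaves),
                 descriptor_bits = as.integer(descriptor_bits),
                 matcher = matcher, ratio = ratio,
                 grayscale_weights = grayscale_weights,
                 max_keypoints = as.integer(max_keypoints),
                 score_space = score_space),
            class = "similarity_config")
}

#' Preprocess an image for feature matching
#'
#' Grayscale conversion followed by resizing to a uniform square working
#' size (default 256 x 256): multi-channel input is collapsed with the
#' configured weights and the image is resampled with area-weighted
#' interpolation (exact block averaging for integer downscales; an
#' already-target-size grayscale image passes through unchanged).
#'
#' @param image [projection_image()], 2D matrix, or h x w x c array with
#'   values in \[0, 255\].
#' @param config a [similarity_config()].
#' @return numeric matrix `target_size` x `target_size`, values in
#'   \[0, 255\].
#' @export
preprocess_image <- function(image, config = similarity_config()) {
  m <- if (inherits(image, "projection_image")) image$pixels else image
  if (is.array(m) && length(dim(m)) == 3L) {
    w <- config$grayscale_weights
    m <- m[, , 1] * w[1] + m[, , 2] * w[2] + m[, , 3] * w[3]
  }
  if (!is.matrix(m) || length(m) == 0) stop("`image` must be a non-empty 2D image")
  resize_area(m, config$target_size, config$target_size)
}

# separable area-weighted resampling: output pixel = overlap-weighted mean
# of the input pixels it covers (identity when sizes match)
resize_area <- function(m, h_out, w_out) {
  Wr <- area_weights(nrow(m), h_out)
  Wc <- area_weights(ncol(m), w_out)
  Wr %*% m %*% t(Wc)
}

area_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Detect scale-space keypoints and binary descriptors
#'
#' Evolves the image through a Perona-Malik nonlinear-diffusion scale space
#' (conductance g = 1 / (1 + |grad|^2 / K^2), contrast K set to the 70th
#' percentile of the gradient magnitude), computes the scale-normalized
#' determinant-of-Hessian response at each level, and keeps 3x3x3
#' scale-space maxima above the configured threshold. Each keypoint gets an
#' upright binary descriptor: mean intensity and mean x/y derivative are
#' sampled over nested 2x2, 3x3 and 4x4 grids of cells covering a patch of
#' radius 9 sigma, and all within-grid cell pairs are compared per channel
#' (486 bits). Featureless images yield an empty set, not an error; the
#' output is deterministic for fixed input and config, sorted by response
#' descending.
#'
#' @param image preprocessed matrix (see [preprocess_image()]) or any input
#'   it accepts.
#' @param config a [similarity_config()].
#' @return list of class `keypoint_set`: `keypoints` data.frame (`x`, `y`,
#'   `scale`, `orientation`, `response`) and `descriptors` logical matrix
#'   (one row per keypoint).
#' @export
detect_and_describe <- function(image, config = similarity_config()) {
  img <- preprocess_image(image, config) / 255
  n <- nrow(img)

  empty <- function() {
    structure(list(
      keypoints = data.frame(x = numeric(), y = numeric(),
                             scale = numeric(), orientation = numeric(),
                             response = numeric()),
      descriptors = matrix(FALSE, 0, config$descriptor_bits)),
      class = "keypoint_set")
  }

  gx <- (cbind(img[, -1], img[, ncol(img)]) - cbind(img[, 1], img[, -ncol(img)])) / 2
  gy <- (rbind(img[-1, ], img[nrow(img), ]) - rbind(img[1, ], img[-nrow(img), ])) / 2
  gmag <- sqrt(gx^2 + gy^2)
  # contrast constant: 70th percentile of the meaningful gradient
  # magnitudes. Numerically negligible gradients (< 1% of the maximum, e.g.
  # the floating-point tails around an isolated blob) are excluded — they
  # would drag the percentile to ~0, stall the diffusion, and leave the
  # response monotone in scale with no extrema anywhere.
  pos <- gmag[gmag > 0.01 * max(gmag)]
  if (length(pos) == 0) return(empty())
  K <- max(quantile(pos, 0.7, names = FALSE), 1e-4)

  S <- 3L
  nlev <- config$n_octaves * S + 1L
  sigmas <- 1.6 * 2^((seq_len(nlev) - 1) / S)
  times <- 0.5 * sigmas^2
  levels <- cpp_pm_diffuse(img, times, 0.24, K)

  resp <- vector("list", nlev)
  deriv <- vector("list", nlev)
  for (i in seq_len(nlev)) {
    h <- max(1L, as.integer(round(sigmas[i] / 2)))
    L <- levels[[i]]
    Lx <- (shift2(L, 0, h) - shift2(L, 0, -h)) / (2 * h)
    Ly <- (shift2(L, h, 0) - shift2(L, -h, 0)) / (2 * h)
    Lxx <- (shift2(L, 0, h) - 2 * L + shift2(L, 0, -h)) / h^2
    Lyy <- (shift2(L, h, 0) - 2 * L + shift2(L, -h, 0)) / h^2
    Lxy <- (shift2(L, h, h) + shift2(L, -h, -h) -
              shift2(L, h, -h) - shift2(L, -h, h)) / (4 * h^2)
    resp[[i]] <- sigmas[i]^4 * (Lxx * Lyy - Lxy^2)
    deriv[[i]] <- list(L = L, Lx = Lx, Ly = Ly)
  }

  kp <- list()
  for (i in 2:(nlev - 1L)) {
    r <- resp[[i]]
    ismax <- r > config$detector_threshold
    for (dd in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                    c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      ismax <- ismax & r > shift2(r, dd[1], dd[2])
    }
    for (j in c(i - 1L, i + 1L)) {
      rj <- resp[[j]]
      for (dd in list(c(0, 0), c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                      c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
        ismax <- ismax & r > shift2(rj, dd[1], dd[2])
      }
    }
    margin <- max(2L, as.integer(round(sigmas[i] / 2)) + 1L)
    ismax[c(seq_len(margin), n - seq_len(margin) + 1L), ] <- FALSE
    ismax[, c(seq_len(margin), n - seq_len(margin) + 1L)] <- FALSE
    hit <- which(ismax, arr.ind = TRUE)
    if (nrow(hit)) {
      kp[[length(kp) + 1L]] <- data.frame(
        x = hit[, 2], y = hit[, 1], scale = sigmas[i], orientation = 0,
        response = r[hit], level = i)
    }
  }
  if (length(kp) == 0) return(empty())
  kp <- do.call(rbind, kp)
  kp <- kp[order(-kp$response, kp$y, kp$x), , drop = FALSE]
  kp <- head(kp, config$max_keypoints)
  rownames(kp) <- NULL

  desc <- matrix(FALSE, nrow(kp), 486L)
  for (q in seq_len(nrow(kp))) {
    desc[q, ] <- describe_keypoint(kp$y[q], kp$x[q], kp$scale[q],
                                   deriv[[kp$level[q]]], n)
  }
  structure(list(keypoints = kp[, c("x", "y", "scale", "orientation",
                                    "response")],
                 descriptors = desc[, seq_len(config$descriptor_bits),
                                    drop = FALSE]),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d keypoints, %d-bit descriptors\n",
              nrow(x$keypoints), ncol(x$descriptors)))
  invisible(x)
}

# shift a matrix by (dr, dc) with edge replication
shift2 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# 486-bit upright descriptor from nested cell grids
describe_keypoint <- function(y0, x0, sigma, lev, n) {
  R <- 9 * sigma
  bits <- logical(0)
  for (g in c(2L, 3L, 4L)) {
    cell <- 2 * R / g
    centers <- -R + (seq_len(g) - 0.5) * cell
    offs <- c(-0.3, 0, 0.3) * cell
    vals <- matrix(0, g * g, 3)
    k <- 0L
    for (cy in centers) for (cx in centers) {
      k <- k + 1L
      ry <- pmin(pmax(round(y0 + cy + offs), 1L), n)
      rx <- pmin(pmax(round(x0 + cx + offs), 1L), n)
      ii <- cbind(rep(ry, each = 3L), rep(rx, times = 3L))
      vals[k, 1] <- mean(lev$L[ii])
      vals[k, 2] <- mean(lev$Lx[ii])
      vals[k, 3] <- mean(lev$Ly[ii])
    }
    pr <- which(upper.tri(matrix(0, g * g, g * g)), arr.ind = TRUE)
    for (ch in 1:3) {
      bits <- c(bits, vals[pr[, 1], ch] > vals[pr[, 2], ch])
    }
  }
  bits
}

#' Match two keypoint sets by Hamming distance
#'
#' Brute-force descriptor matching. The default symmetric matcher keeps a
#' pair (i, j) iff j is i's nearest neighbor in `b` and i is j's nearest in
#' `a` (ties broken toward the lower index), which is parameter-free,
#' one-to-one, and symmetric in its arguments. The similarity score is the
#' arithmetic mean of the kept pair distances — Hamming (descriptor bits)
#' by default, or image-space displacement when the config says so. With no
#' keypoints or no surviving pairs the score is `NA` and `flag_undefined`
#' is set (never reported as 0).
#'
#' @param a,b `keypoint_set`s with equal descriptor lengths.
#' @param config a [similarity_config()].
#' @return list of class `match_result`: `pairs` data.frame (`index_a`,
#'   `index_b`, `distance`), `similarity_score`, `n_keypoints_a`,
#'   `n_keypoints_b`, `n_matches`, `flag_undefined`.
#' @export
match_features <- function(a, b, config = similarity_config()) {
  stopifnot(inherits(a, "keypoint_set"), inherits(b, "keypoint_set"))
  if (ncol(a$descriptors) != ncol(b$descriptors)) {
    stop("descriptor lengths differ (", ncol(a$descriptors), " vs ",
         ncol(b$descriptors), ")")
  }
  na <- nrow(a$keypoints); nb <- nrow(b$keypoints)
  mk <- function(pairs) {
    nm <- nrow(pairs)
    score <- if (nm > 0) mean(pairs$distance) else NA_real_
    structure(list(pairs = pairs, similarity_score = score,
                   n_keypoints_a = na, n_keypoints_b = nb, n_matches = nm,
                   flag_undefined = nm == 0),
              class = "match_result")
  }
  if (na == 0 || nb == 0) {
    return(mk(data.frame(index_a = integer(), index_b = integer(),
                         distance = numeric())))
  }
  D <- hamming_matrix(a$descriptors, b$descriptors)
  if (config$matcher == "bruteforce-symmetric") {
    nn_ab <- apply(D, 1, which.min) # first index on ties
    nn_ba <- apply(D, 2, which.min)
    ia <- which(nn_ba[nn_ab] == seq_len(na))
    pairs <- data.frame(index_a = ia, index_b = nn_ab[ia],
                        distance = D[cbind(ia, nn_ab[ia])])
  } else {
    keep <- integer(0); dist <- numeric(0); tgt <- integer(0)
    for (i in seq_len(na)) {
      o <- order(D[i, ])
      d1 <- D[i, o[1]]
      d2 <- if (nb > 1) D[i, o[2]] else Inf
      if (d1 <= config$ratio * d2) {
        keep <- c(keep, i); tgt <- c(tgt, o[1]); dist <- c(dist, d1)
      }
    }
    # enforce one-to-one: for duplicated targets keep the closest
    ok <- rep(TRUE, length(keep))
    for (j in unique(tgt)) {
      w <- which(tgt == j)
      if (length(w) > 1) ok[w[-which.min(dist[w])]] <- FALSE
    }
    pairs <- data.frame(index_a = keep[ok], index_b = tgt[ok],
                        distance = dist[ok])
  }
  if (config$score_space == "spatial" && nrow(pairs) > 0) {
    pairs$distance <- sqrt(
      (a$keypoints$x[pairs$index_a] - b$keypoints$x[pairs$index_b])^2 +
        (a$keypoints$y[pairs$index_a] - b$keypoints$y[pairs$index_b])^2)
  }
  mk(pairs)
}

# pairwise Hamming distances between 0/1 descriptor matrices
hamming_matrix <- function(A, B) {
  A <- A * 1
  B <- B * 1
  A %*% (1 - t(B)) + (1 - A) %*% t(B)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d matches (%d vs %d keypoints), similarity score %s\n",
    x$n_matches, x$n_keypoints_a, x$n_keypoints_b,
    if (x$flag_undefined) "undefined" else sprintf("%.3f",
                                                   x$similarity_score)))
  invisible(x)
}

#' Similarity score between two renders
#'
#' The full 2.5D pipeline: preprocess both images (grayscale, 256 x 256),
#' detect keypoints and binary descriptors in each, match them, and report
#' the similarity score — the mean distance over matched feature pairs.
#' A lower score means more similar images.
#'
#' @param image_a,image_b renders ([projection_image()], matrix or RGB
#'   array).
#' @param config a [similarity_config()].
#' @return A `match_result` with the config recorded as attribute
#'   `"config"`.
#' @export
similarity_score <- function(image_a, image_b,
                             config = similarity_config()) {
  ka <- detect_and_describe(image_a, config)
  kb <- detect_and_describe(image_b, config)
  res <- match_features(ka, kb, config)
  attr(res, "config") <- config
  res
}
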