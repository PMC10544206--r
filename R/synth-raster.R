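#' Rasterize a vessel tree into a 3D volume image
#'
#' Paints the tree into an anisotropic voxel grid with all distances
#' computed in physical um, so anisotropic spacing yields correct tube
#' cross-sections. The `"EC"` channel paints every edge as a solid tube of
#' its radius; the `"SMA"` channel paints an annular wall shell of thickness
#' `wall_thickness_fraction x radius` around **baseline** edges only —
#' neovessel sprouts are unmuscularized, as newly formed vessels have not
#' yet acquired a smooth-muscle coat. The `"nuclei"` channel scatters
#' small nuclear blobs through the lung region. Noise (Poisson shot noise on
#' signal, then constant background plus Gaussian read noise) is applied
#' after the geometry and is reproducible from `params$seed`.
#'
#' Tubes are rasterized by a per-voxel distance-to-segment test within each
#' segment's bounding box: exact and simple at desk scale.
#'
#' @param tree a [vessel_tree()]; must fit inside
#'   `params$volume_shape * params$spacing`.
#' @param params the [synth_params()] describing grid, wall and noise.
#' @param channel `"EC"`, `"SMA"` or `"nuclei"`.
#' @return A [volume_image()].
#' @export
rasterize_tree <- function(tree, params, channel = c("EC", "SMA", "nuclei")) {
  channel <- match.arg(channel)
  stopifnot(inherits(tree, "vessel_tree"), inherits(params, "synth_params"))
  shape <- params$volume_shape
  sp <- params$spacing
  extent <- shape * sp

  bad <- which(tree$nodes$z < 0 | tree$nodes$z > extent[1] |
                 tree$nodes$y < 0 | tree$nodes$y > extent[2] |
                 tree$nodes$x < 0 | tree$nodes$x > extent[3])
  if (length(bad)) {
    stop("tree extends outside the volume at node(s) ",
         paste(tree$nodes$id[bad], collapse = ", "))
  }

  vol <- array(0, shape)
  wtf <- params$wall_thickness_fraction

  if (channel %in% c("EC", "SMA")) {
    fg <- if (channel == "EC") 180 else 160
    for (i in seq_len(nrow(tree$edges))) {
      e <- tree$edges[i, ]
      if (channel == "SMA" && e$label != "baseline") next
      pl <- edge_polyline(tree, i)
      r <- e$radius
      rmax <- if (channel == "SMA") r * (1 + wtf) else r
      for (s in seq_len(nrow(pl) - 1L)) {
        vol <- paint_capsule(vol, sp, pl[s, ], pl[s + 1L, ], r, rmax,
                             channel, fg)
      }
    }
  } else {
    # nuclei: random 2.5 um blobs inside the lung region, one per ~1e5 um^3
    boundary <- tree$metadata$lung_boundary
    vol <- with_seed(params$seed + 303L, {
      n_nuc <- max(1L, round(prod(extent) * 1e-5))
      for (k in seq_len(n_nuc)) {
        p <- boundary$center + runif(3, -1, 1) * boundary$semiaxes
        if (ellipsoid_frac(p, boundary) > 0.95) next
        vol <- paint_capsule(vol, sp, p, p + 1e-6, 2.5, 2.5, "EC", 140)
      }
      vol
    })
  }

  seed_off <- c(EC = 101L, SMA = 202L, nuclei = 303L)[[channel]]
  vol <- with_seed(params$seed + seed_off, {
    sig <- vol
    if (params$shot_noise_scale > 0) {
      sig <- array(rpois(length(sig), sig / params$shot_noise_scale) *
                     params$shot_noise_scale, dim(sig))
    }
    sig <- sig + params$background_level
    if (params$gaussian_noise_sd > 0) {
      sig <- sig + array(rnorm(length(sig), 0, params$gaussian_noise_sd),
                         dim(sig))
    }
    sig
  })
  vol <- pmin(pmax(round(vol), 0), 255)
  volume_image(vol, sp, channel, bit_depth = 8L)
}

# paint one capsule (segment a-b with radius window) into vol; for the SMA
# channel only the annular shell (r, rmax] is painted
paint_capsule <- function(vol, sp, a, b, r, rmax, channel, fg) {
  shape <- dim(vol)
  lo <- pmin(a, b) - rmax
  hi <- pmax(a, b) + rmax
  i0 <- pmax(1L, as.integer(ceiling(lo / sp + 0.5 - 1e-9)))
  i1 <- pmin(shape, as.integer(floor(hi / sp + 0.5 + 1e-9)))
  if (any(i0 > i1)) return(vol)
  zc <- (seq(i0[1], i1[1]) - 0.5) * sp[1]
  yc <- (seq(i0[2], i1[2]) - 0.5) * sp[2]
  xc <- (seq(i0[3], i1[3]) - 0.5) * sp[3]
  nb <- c(length(zc), length(yc), length(xc))
  Z <- array(rep(zc, times = nb[2] * nb[3]), nb)
  Y <- array(rep(rep(yc, each = nb[1]), times = nb[3]), nb)
  X <- array(rep(xc, each = nb[1] * nb[2]), nb)
  u <- b - a
  L2 <- sum(u^2)
  if (L2 == 0) {
    d2 <- (Z - a[1])^2 + (Y - a[2])^2 + (X - a[3])^2
  } else {
    t <- ((Z - a[1]) * u[1] + (Y - a[2]) * u[2] + (X - a[3]) * u[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (Z - a[1] - t * u[1])^2 + (Y - a[2] - t * u[2])^2 +
      (X - a[3] - t * u[3])^2
  }
  sel <- if (channel == "SMA") d2 > r^2 & d2 <= rmax^2 else d2 <= rmax^2
  sub <- vol[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  vol[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- pmax(sub, fg * sel)
  vol
}

#' Render a 2D projection of a volume
#'
#' The "2.5D" representation used for image comparison: a 2D render of the
#' 3D stack along one axis, rescaled to 8 bits.
#'
#' @param volume a [volume_image()].
#' @param axis projection axis: `"z"` (default, giving a y-x view), `"y"`,
#'   or `"x"`.
#' @param mode `"mip"` for maximum-intensity projection, or `"depth"` for a
#'   depth-shaded render in which the maximum is attenuated by how deep
#'   along the axis it occurs.
#' @return A [projection_image()] (8-bit, rescaled so the brightest pixel
#'   is 255).
#' @export
render_projection <- function(volume, axis = c("z", "y", "x"),
                              mode = c("mip", "depth")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "volume_image"))
  ax <- match(axis, c("z", "y", "x"))
  keep <- setdiff(1:3, ax)
  v <- volume$voxels
  if (mode == "mip") {
    m <- apply(v, keep, max)
  } else {
    n <- dim(v)[ax]
    m <- apply(v, keep, function(col) {
      i <- which.max(col)
      col[i] * (1 - 0.6 * (i - 1) / max(1, n - 1))
    })
  }
  mx <- max(m)
  pix <- if (mx > 0) round(255 * m / mx) else m
  projection_image(pix, axis = axis, mode = mode,
                   pixel_size = volume$spacing[keep])
}

#' Apply a graded perturbation to a projection image
#'
#' Test harness for the similarity score's discriminative behavior: applies
#' a composition of rotation, smooth elastic warp, and added tube segments
#' whose magnitude increases strictly with `level`. Level 0 is the
#' identity; all randomness (warp field, rotation direction, tube
#' positions) is frozen by `seed` and only *scaled* by `level`, so the
#' perturbation series is nested and deterministic.
#'
#' @param image a [projection_image()] or numeric matrix in \[0, 255\].
#' @param level integer >= 0; degradation magnitude (rotation of
#'   1.5 degrees, warp amplitude of 0.8 px and one extra tube segment per
#'   level).
#' @param seed integer seed freezing the perturbation.
#' @param max_level largest level for which tube segments are pregenerated.
#' @return A [projection_image()] of the same size.
#' @export
perturb_projection <- function(image, level, seed = 1L, max_level = 8L) {
  pix <- if (inherits(image, "projection_image")) image$pixels else image
  stopifnot(is.matrix(pix), level >= 0, level == round(level))
  if (level == 0) {
    return(if (inherits(image, "projection_image")) image
           else projection_image(pix))
  }
  h <- nrow(pix); w <- ncol(pix)
  plan <- with_seed(seed, {
    list(
      fr = matrix(rnorm(100), 10, 10),
      fc = matrix(rnorm(100), 10, 10),
      sgn = sample(c(-1, 1), 1),
      tubes = data.frame(
        r1 = runif(max_level, 0.1, 0.9) * h,
        c1 = runif(max_level, 0.1, 0.9) * w,
        ang = runif(max_level, 0, 2 * pi),
        len = runif(max_level, 0.1, 0.25) * min(h, w)
      )
    )
  })
  src <- pix
  # add the first `level` tube segments (width 1.5 px, bright)
  nt <- min(level, max_level)
  for (k in seq_len(nt)) {
    t <- plan$tubes[k, ]
    a <- c(t$r1, t$c1)
    b <- a + t$len * c(sin(t$ang), cos(t$ang))
    src <- draw_segment2d(src, a, b, 1.5, 200)
  }
  # inverse-map rotation + elastic warp, bilinear sampling
  ang <- plan$sgn * 1.5 * level * pi / 180
  amp <- 0.8 * level
  dr <- upsample_bilinear(plan$fr / max(abs(plan$fr)), h, w) * amp
  dc <- upsample_bilinear(plan$fc / max(abs(plan$fc)), h, w) * amp
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  R <- matrix(rep(seq_len(h), w), h, w)
  C <- matrix(rep(seq_len(w), each = h), h, w)
  rs <- ctr[1] + cos(ang) * (R - ctr[1]) - sin(ang) * (C - ctr[2]) + dr
  cs <- ctr[2] + sin(ang) * (R - ctr[1]) + cos(ang) * (C - ctr[2]) + dc
  out <- sample_bilinear(src, rs, cs)
  out <- pmin(pmax(round(out), 0), 255)
  res <- projection_image(out)
  if (inherits(image, "projection_image")) {
    res$axis <- image$axis; res$mode <- image$mode
    res$pixel_size <- image$pixel_size
  }
  res
}

# draw a thick bright segment into a matrix (row/col coordinates)
draw_segment2d <- function(m, a, b, width, val) {
  h <- nrow(m); w <- ncol(m)
  lo <- pmax(1, floor(pmin(a, b) - width))
  hi <- pmin(c(h, w), ceiling(pmax(a, b) + width))
  if (any(lo > hi)) return(m)
  rr <- lo[1]:hi[1]; cc <- lo[2]:hi[2]
  R <- matrix(rep(rr, length(cc)), length(rr))
  C <- matrix(rep(cc, each = length(rr)), length(rr))
  u <- b - a; L2 <- sum(u^2)
  t <- if (L2 == 0) 0 else pmin(pmax(((R - a[1]) * u[1] + (C - a[2]) * u[2]) / L2, 0), 1)
  d2 <- (R - a[1] - t * u[1])^2 + (C - a[2] - t * u[2])^2
  sub <- m[rr, cc, drop = FALSE]
  m[rr, cc] <- pmax(sub, val * (d2 <= width^2))
  m
}

# bilinear upsample of a coarse field to h x w
upsample_bilinear <- function(f, h, w) {
  nr <- nrow(f); nc <- ncol(f)
  rs <- seq(1, nr, length.out = h)
  cs <- seq(1, nc, length.out = w)
  r0 <- pmin(floor(rs), nr - 1); c0 <- pmin(floor(cs), nc - 1)
  ar <- rs - r0; ac <- cs - c0
  f00 <- f[r0, c0, drop = FALSE]; f10 <- f[r0 + 1, c0, drop = FALSE]
  f01 <- f[r0, c0 + 1, drop = FALSE]; f11 <- f[r0 + 1, c0 + 1, drop = FALSE]
  AR <- matrix(ar, h, w); AC <- matrix(ac, h, w, byrow = TRUE)
  f00 * (1 - AR) * (1 - AC) + f10 * AR * (1 - AC) +
    f01 * (1 - AR) * AC + f11 * AR * AC
}

# bilinear sampling of matrix m at fractional (rs, cs); outside -> 0
sample_bilinear <- function(m, rs, cs) {
  h <- nrow(m); w <- ncol(m)
  inside <- rs >= 1 & rs <= h & cs >= 1 & cs <= w
  rs <- pmin(pmax(rs, 1), h); cs <- pmin(pmax(cs, 1), w)
  r0 <- pmin(floor(rs), h - 1); c0 <- pmin(floor(cs), w - 1)
  ar <- rs - r0; ac <- cs - c0
  rv <- as.vector(r0); cv <- as.vector(c0)
  v <- m[cbind(rv, cv)] * (1 - ar) * (1 - ac) +
    m[cbind(rv + 1, cv)] * ar * (1 - ac) +
    m[cbind(rv, cv + 1)] * (1 - ar) * ac +
    m[cbind(rv + 1, cv + 1)] * ar * ac
  out <- matrix(v, h, w)
  out[!inside] <- 0
  out
}

#' Simulate a per-animal measurement table
#'
#' Draws independent normal samples per experimental group, mirroring the
#' per-mouse measurement tables (RVSP, Fulton's index, wall thickness, ...)
#' that the group-comparison statistics consume.
#'
#' @param group_means,group_sds equal-length numeric vectors; SDs must be
#'   >= 0 (0 gives degenerate, exactly-equal samples).
#' @param n_per_group animals per group: scalar (recycled) or vector, all
#'   >= 2.
#' @param seed integer seed; identical seeds reproduce identical tables.
#' @param group_labels optional character labels (defaults to `group1`...).
#' @return data.frame with columns `group` (factor), `animal_id`, `value`.
#' @export
simulate_group_table <- function(group_means, group_sds, n_per_group,
                                 seed = 1L, group_labels = NULL) {
  k <- length(group_means)
  if (length(group_sds) != k) {
    stop("`group_means` and `group_sds` must have equal length")
  }
  if (any(group_sds < 0)) stop("`group_sds` must be >= 0")
  n <- rep_len(n_per_group, k)
  if (any(n < 2)) stop("`n_per_group` must be >= 2")
  labels <- group_labels %||% paste0("group", seq_len(k))
  with_seed(seed, {
    rows <- lapply(seq_len(k), function(g) {
      data.frame(group = labels[g],
                 animal_id = sprintf("%s_%02d", labels[g], seq_len(n[g])),
                 value = rnorm(n[g], group_means[g], group_sds[g]))
    })
    out <- do.call(rbind, rows)
    out$group <- factor(out$group, levels = labels)
    rownames(out) <- NULL
    out
  })
}
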