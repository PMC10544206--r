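#' Parameters for the synthetic vascular-volume generator
#'
#' Bundles every knob of the synthetic 3D phantom: geometry of the branching,
#' tapering vascular tree, the hypoxia-style neovessel sprouts appended to
#' terminal branches, the smooth-muscle wall layer, the imaging grid, and the
#' noise model. Identical parameter sets (including `seed`) reproduce
#' bit-identical trees and volumes.
#'
#' The default imaging grid uses the high-magnification multiphoton geometry
#' (1.13 um in-plane, 2.2 um z-step); [voxel_geometry()] gives the two
#' lower-magnification alternatives (2.27/6.6 and 4.54/13.2 um).
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param volume_shape integer vector of 3 voxel counts, z-y-x order.
#' @param spacing numeric vector of 3 voxel spacings in um, z-y-x order.
#' @param n_root_vessels number of root vessels entering at the hilum.
#' @param branch_generations number of dichotomous branching generations.
#' @param branch_angle_spread branching angle spread in degrees.
#' @param taper_ratio child/parent radius ratio, in (0, 1].
#' @param root_radius radius of the root vessels in um.
#' @param wall_thickness_fraction smooth-muscle wall thickness as a fraction
#'   of the local vessel radius, in (0, 1).
#' @param n_sprouts number of neovessel sprouts appended to terminal
#'   baseline branches (0 = normoxia-like network).
#' @param sprout_length_mean,sprout_length_sd mean and SD (um) of the
#'   sprout-length distribution (normal truncated at 0).
#' @param elongation_factor radial scaling (>= 1) applied to terminal
#'   baseline tips, measured from the hilum; models elongation of
#'   muscularized vessels toward the pleural boundary.
#' @param background_level,shot_noise_scale,gaussian_noise_sd noise model:
#'   constant background offset, Poisson shot-noise gain (0 disables), and
#'   additive Gaussian SD, all in intensity units.
#' @return An object of class `synth_params` (a validated list).
#' @seealso [generate_vessel_tree()], [rasterize_tree()], [preset_params()]
#' @export
synth_params <- function(seed = 1L,
                         volume_shape = c(96L, 224L, 224L),
                         spacing = voxel_geometry("x20"),
                         n_root_vessels = 2L,
                         branch_generations = 4L,
                         branch_angle_spread = 40,
                         taper_ratio = 0.8,
                         root_radius = 8,
                         wall_thickness_fraction = 0.25,
                         n_sprouts = 0L,
                         sprout_length_mean = 60,
                         sprout_length_sd = 15,
                         elongation_factor = 1,
                         background_level = 8,
                         shot_noise_scale = 1,
                         gaussian_noise_sd = 2) {
  if (length(volume_shape) != 3L || any(volume_shape < 1) ||
      any(volume_shape != round(volume_shape))) {
    stop("`volume_shape` must be 3 positive integers (z, y, x)")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive reals (um, z-y-x)")
  }
  stopifnot_scalar_num(root_radius, "root_radius", positive = TRUE)
  if (taper_ratio <= 0 || taper_ratio > 1) stop("`taper_ratio` must be in (0, 1]")
  if (wall_thickness_fraction <= 0 || wall_thickness_fraction >= 1) {
    stop("`wall_thickness_fraction` must be in (0, 1)")
  }
  if (n_root_vessels < 1) stop("`n_root_vessels` must be >= 1")
  if (branch_generations < 1) stop("`branch_generations` must be >= 1")
  if (n_sprouts < 0) stop("`n_sprouts` must be >= 0")
  if (elongation_factor < 1) stop("`elongation_factor` must be >= 1")
  if (sprout_length_sd < 0) stop("`sprout_length_sd` must be >= 0")
  p <- list(
    seed = as.integer(seed),
    volume_shape = as.integer(volume_shape),
    spacing = as.numeric(spacing),
    n_root_vessels = as.integer(n_root_vessels),
    branch_generations = as.integer(branch_generations),
    branch_angle_spread = branch_angle_spread,
    taper_ratio = taper_ratio,
    root_radius = root_radius,
    wall_thickness_fraction = wall_thickness_fraction,
    n_sprouts = as.integer(n_sprouts),
    sprout_length_mean = sprout_length_mean,
    sprout_length_sd = sprout_length_sd,
    elongation_factor = elongation_factor,
    background_level = background_level,
    shot_noise_scale = shot_noise_scale,
    gaussian_noise_sd = gaussian_noise_sd
  )
  structure(p, class = "synth_params")
}

#' Multiphoton voxel geometries
#'
#' The three acquisition geometries of the imaging setup being emulated:
#' in-plane pixel sizes of 4.54, 2.27 and 1.13 um at the x5, x10 and x20
#' objectives, with z-steps of 13.2, 6.6 and 2.2 um respectively.
#'
#' @param objective one of `"x5"`, `"x10"`, `"x20"`.
#' @return numeric vector of 3 spacings in um, z-y-x order.
#' @export
voxel_geometry <- function(objective = c("x20", "x10", "x5")) {
  objective <- match.arg(objective)
  switch(objective,
    x5 = c(13.2, 4.54, 4.54),
    x10 = c(6.6, 2.27, 2.27),
    x20 = c(2.2, 1.13, 1.13)
  )
}

#' Lung boundary descriptor
#'
#' The pleural boundary is modeled as an axis-aligned ellipsoid with a
#' designated hilum point on its surface (the medial entry point of the
#' vasculature). All coordinates in um, z-y-x order.
#'
#' @param center ellipsoid center (um, z-y-x).
#' @param semiaxes ellipsoid semi-axes (um, z-y-x), all > 0.
#' @param hilum hilum point (um, z-y-x); must lie on (or within 1% of) the
#'   ellipsoid surface.
#' @return An object of class `lung_boundary`.
#' @export
lung_boundary <- function(center, semiaxes, hilum) {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L, length(hilum) == 3L)
  if (any(semiaxes <= 0)) stop("`semiaxes` must be strictly positive")
  r <- sqrt(sum(((hilum - center) / semiaxes)^2))
  if (abs(r - 1) > 0.01) {
    stop("`hilum` must lie on the ellipsoid surface (radial fraction ",
         signif(r, 4), ")")
  }
  structure(list(center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 hilum = as.numeric(hilum)),
            class = "lung_boundary")
}

# squared normalized radial coordinate of p in the ellipsoid (1 = surface)
ellipsoid_frac <- function(p, boundary) {
  sqrt(sum(((p - boundary$center) / boundary$semiaxes)^2))
}

# fraction of the hilum-to-boundary ray at which p sits: 0 at the hilum,
# 1 where the ray through p meets the ellipsoid surface
ray_fraction <- function(p, boundary) {
  h <- boundary$hilum
  d <- (p - h) / boundary$semiaxes
  hc <- (h - boundary$center) / boundary$semiaxes
  if (sum(hc^2) > 1 + 1e-9) stop("hilum lies outside the boundary ellipsoid")
  a <- sum(d^2)
  if (a == 0) return(0)
  b <- 2 * sum(hc * d)
  cc <- sum(hc^2) - 1
  s <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a) # positive root: boundary hit
  1 / s
}

#' Construct a 3D volume image
#'
#' A thin container for an anisotropic 3D intensity grid: the stand-in for a
#' cleared-lung multiphoton stack. Dimensions and spacing are z-y-x ordered;
#' all lengths are physical um.
#'
#' @param voxels 3D numeric array, dim = (nz, ny, nx), non-negative
#'   intensities within the bit-depth range.
#' @param spacing voxel spacing in um (z, y, x), strictly positive.
#' @param channel stain label: `"EC"` (endothelial / lineage label), `"SMA"`
#'   (smooth-muscle wall) or `"nuclei"`.
#' @param bit_depth 8 or 16.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing, channel = c("EC", "SMA", "nuclei"),
                         bit_depth = 8L) {
  channel <- match.arg(channel)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array (z, y, x)")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive um values (z, y, x)")
  }
  vmax <- 2^bit_depth - 1
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > vmax) {
    stop("intensities must lie in [0, ", vmax, "]")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 channel = channel, bit_depth = as.integer(bit_depth)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_image> %s channel, %d x %d x %d voxels (z,y,x), spacing %s um, %d-bit\n",
    x$channel, d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "/"),
    x$bit_depth))
  invisible(x)
}

#' Construct a 2D projection image
#'
#' An 8-bit 2D render of a volume (the "2.5D" representation used for
#' feature matching).
#'
#' @param pixels 2D numeric matrix with values in \[0, 255\].
#' @param axis projection axis the render was taken along (`"z"`, `"y"`,
#'   `"x"`).
#' @param mode `"mip"` (maximum-intensity) or `"depth"` (depth-shaded).
#' @param pixel_size pixel size(s) in um (length 1 or 2, row/column order).
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(pixels, axis = "z", mode = "mip",
                             pixel_size = 1) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, axis = axis, mode = mode,
                 pixel_size = as.numeric(pixel_size)),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px, axis %s, mode %s, %s um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$axis, x$mode,
              paste(signif(x$pixel_size, 4), collapse = "/")))
  invisible(x)
}

#' Construct a vessel tree
#'
#' Geometric graph of a vascular network: nodes carry 3D um coordinates and
#' radii, edges carry polyline geometry, physical length and a
#' baseline/neovessel label. Used both as generator ground truth and as the
#' output of skeletonization.
#'
#' @param nodes data.frame with columns `id`, `z`, `y`, `x`, `radius`.
#' @param edges data.frame with columns `from`, `to`, `label`
#'   (`"baseline"`/`"neovessel"`), `length`, `radius`.
#' @param polylines list (one per edge row) of n x 3 matrices of um
#'   coordinates (z, y, x); first and last rows must coincide with the
#'   `from`/`to` node coordinates. `NULL` entries mean straight segments.
#' @param metadata list with `lung_boundary`, `hilum`,
#'   `total_baseline_length`, `total_neovessel_length`.
#' @return An object of class `vessel_tree`.
#' @export
vessel_tree <- function(nodes, edges, polylines = NULL, metadata = list()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (is.null(polylines)) polylines <- vector("list", nrow(edges))
  if (length(polylines) != nrow(edges)) {
    stop("`polylines` must have one entry per edge")
  }
  tree <- structure(list(nodes = nodes, edges = edges, polylines = polylines,
                         metadata = metadata),
                    class = "vessel_tree")
  # length bookkeeping must be exact: recompute and compare
  len <- edge_lengths(tree)
  if (any(abs(len - edges$length) > 1e-6)) {
    stop("edge `length` disagrees with polyline geometry (> 1e-6 um)")
  }
  tree
}

# physical polyline length of every edge, recomputed from coordinates
edge_lengths <- function(tree) {
  vapply(seq_len(nrow(tree$edges)), function(i) {
    pl <- edge_polyline(tree, i)
    sum(sqrt(rowSums((pl[-1, , drop = FALSE] -
                        pl[-nrow(pl), , drop = FALSE])^2)))
  }, numeric(1))
}

# polyline coordinates (n x 3, um) of edge i, falling back to the straight
# segment between its endpoint nodes
edge_polyline <- function(tree, i) {
  pl <- tree$polylines[[i]]
  if (!is.null(pl)) return(pl)
  e <- tree$edges[i, ]
  a <- as.numeric(tree$nodes[match(e$from, tree$nodes$id), c("z", "y", "x")])
  b <- as.numeric(tree$nodes[match(e$to, tree$nodes$id), c("z", "y", "x")])
  rbind(a, b)
}

#' @export
print.vessel_tree <- function(x, ...) {
  nb <- sum(x$edges$label == "baseline")
  nn <- sum(x$edges$label == "neovessel")
  cat(sprintf(
    "<vessel_tree> %d nodes, %d edges (%d baseline, %d neovessel)\n",
    nrow(x$nodes), nrow(x$edges), nb, nn))
  if (!is.null(x$metadata$total_baseline_length)) {
    cat(sprintf("  baseline length %.1f um, neovessel length %.1f um\n",
                x$metadata$total_baseline_length,
                x$metadata$total_neovessel_length))
  }
  invisible(x)
}

# node degrees from the edge list
node_degrees <- function(tree) {
  ids <- tree$nodes$id
  tab <- table(factor(c(tree$edges$from, tree$edges$to), levels = ids))
  as.integer(tab)
}
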