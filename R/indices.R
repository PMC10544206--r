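#' Total neovessel length from a post-exposure skeleton
#'
#' Classifies every skeleton branch as pre-existing or newly formed by
#' overlap with the baseline network: the baseline mask is dilated by
#' `dilation_voxels` (tolerating one-voxel registration jitter), and a
#' branch whose fraction of centerline points inside the dilated baseline
#' falls below `overlap_cutoff` is called a neovessel. Because a sprout
#' continues seamlessly from the baseline tip it grew out of, a neovessel
#' branch usually carries a short pre-existing stub at its proximal end;
#' only the centerline portion *outside* the dilated baseline is therefore
#' summed, which removes that systematic overestimate. Returns the total
#' neovessel length in um; the per-branch classification (with both full
#' and outside-baseline lengths) is attached as attribute `"per_edge"`.
#'
#' @param post_skeleton a `skeleton_graph` from [skeletonize_mask()] run on
#'   the post-exposure (or lineage-labeled) mask.
#' @param baseline_mask logical 3D array: the binarized baseline volume,
#'   same grid as the volume the skeleton came from. An empty baseline
#'   means every branch is new.
#' @param spacing voxel spacing in um (z, y, x).
#' @param dilation_voxels Euclidean dilation radius, in voxels.
#' @param overlap_cutoff branch is a neovessel when its fraction of
#'   centerline points inside the dilated baseline is below this value.
#' @return Total neovessel length (um) with attribute `per_edge`.
#' @export
neovessel_length <- function(post_skeleton, baseline_mask, spacing,
                             dilation_voxels = 2, overlap_cutoff = 0.5) {
  stopifnot(inherits(post_skeleton, "vessel_tree"))
  if (is.list(baseline_mask) && !is.null(baseline_mask$mask)) {
    baseline_mask <- baseline_mask$mask
  }
  stopifnot(is.array(baseline_mask), length(dim(baseline_mask)) == 3L)
  dims <- dim(baseline_mask)

  if (!any(baseline_mask)) {
    inside <- function(pl) rep(FALSE, nrow(pl))
  } else {
    # distance (in voxel units) from every voxel to the baseline network
    d2base <- cpp_edt3d(as.integer(baseline_mask == 0), as.integer(dims),
                        c(1, 1, 1))
    dilated <- d2base <= dilation_voxels
    inside <- function(pl) {
      iz <- pmin(pmax(round(pl[, 1] / spacing[1] + 0.5), 1), dims[1])
      iy <- pmin(pmax(round(pl[, 2] / spacing[2] + 0.5), 1), dims[2])
      ix <- pmin(pmax(round(pl[, 3] / spacing[3] + 0.5), 1), dims[3])
      dilated[cbind(iz, iy, ix)]
    }
  }

  ne <- nrow(post_skeleton$edges)
  frac <- numeric(ne)
  out_len <- numeric(ne)
  for (i in seq_len(ne)) {
    pl <- edge_polyline(post_skeleton, i)
    inb <- inside(pl)
    frac[i] <- mean(inb)
    step <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                            pl[-nrow(pl), , drop = FALSE])^2))
    # a step is outside when both of its endpoints are
    step_out <- !inb[-length(inb)] & !inb[-1]
    out_len[i] <- sum(step[step_out])
  }
  is_new <- frac < overlap_cutoff
  per_edge <- data.frame(edge = seq_len(ne),
                         length = post_skeleton$edges$length,
                         outside_length = out_len,
                         baseline_fraction = frac,
                         is_neovessel = is_new)
  structure(sum(per_edge$outside_length[is_new]), per_edge = per_edge)
}

#' Angiogenesis index
#'
#' Total neovessel length normalized by the lung circumference, both in um,
#' giving a dimensionless, scale-invariant measure of the angiogenic
#' response.
#'
#' @param neovessel_length_um total neovessel length (um), e.g. from
#'   [neovessel_length()].
#' @param lung_circumference_um lung circumference (um), > 0, e.g. from
#'   [measure_lung_circumference()].
#' @return `neovessel_length_um / lung_circumference_um`.
#' @seealso [measure_angiogenesis()] for the one-call volume pipeline.
#' @export
angiogenesis_index <- function(neovessel_length_um, lung_circumference_um) {
  stopifnot_scalar_num(neovessel_length_um, "neovessel_length_um")
  stopifnot_scalar_num(lung_circumference_um, "lung_circumference_um",
                       positive = TRUE)
  if (neovessel_length_um < 0) stop("`neovessel_length_um` must be >= 0")
  as.numeric(neovessel_length_um) / lung_circumference_um
}

#' One-call angiogenesis pipeline on two volumes
#'
#' Binarizes the post-exposure and baseline volumes, skeletonizes the
#' post-exposure mask, measures the neovessel length against the baseline
#' network, measures the lung circumference from the boundary descriptor,
#' and returns the angiogenesis index.
#'
#' @param post_volume,baseline_volume [volume_image()]s (or binary arrays)
#'   on the same grid, assumed pre-aligned.
#' @param boundary a [lung_boundary()] descriptor.
#' @param method,fixed_threshold binarization rule, see
#'   [binarize_volume()].
#' @param ... further arguments passed to [neovessel_length()].
#' @return list of class `index_result`: `angiogenesis_index`,
#'   `total_neovessel_length` (um), `lung_circumference` (um).
#' @export
measure_angiogenesis <- function(post_volume, baseline_volume, boundary,
                                 method = "otsu", fixed_threshold = NULL,
                                 ...) {
  spacing <- if (inherits(post_volume, "volume_image")) {
    post_volume$spacing
  } else {
    stop("`post_volume` must be a volume_image (spacing is required)")
  }
  post_mask <- binarize_volume(post_volume, method, fixed_threshold)$mask
  base_mask <- if (inherits(baseline_volume, "volume_image")) {
    binarize_volume(baseline_volume, method, fixed_threshold)$mask
  } else {
    baseline_volume
  }
  skel <- skeletonize_mask(post_mask, spacing)
  nvl <- neovessel_length(skel, base_mask, spacing, ...)
  circ <- measure_lung_circumference(boundary)
  structure(list(angiogenesis_index = angiogenesis_index(nvl, circ),
                 total_neovessel_length = as.numeric(nvl),
                 lung_circumference = circ,
                 per_edge = attr(nvl, "per_edge")),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf(
    "<index_result> angiogenesis index %.4f (neovessel %.1f um / circumference %.1f um)\n",
    x$angiogenesis_index, x$total_neovessel_length, x$lung_circumference))
  invisible(x)
}

#' Measure the lung circumference
#'
#' Perimeter of the pleural outline in um, measured on the mid-axial plane
#' (the plane the 2D renders are taken in). For an analytic
#' [lung_boundary()] the mid-axial cross-section is an ellipse and the
#' perimeter is computed by arc-length quadrature. For a 2D mask (matrix or
#' [projection_image()]) the perimeter of the convex hull of foreground
#' pixel centers is used, which is accurate for convex pleural outlines and
#' immune to pixel-staircase overestimation.
#'
#' @param x a [lung_boundary()], a 2D mask (logical/numeric matrix), or a
#'   [projection_image()].
#' @param pixel_size pixel size in um (scalar or length 2, row/column) for
#'   matrix input.
#' @return circumference in um.
#' @export
measure_lung_circumference <- function(x, pixel_size = 1) {
  UseMethod("measure_lung_circumference")
}

#' @export
measure_lung_circumference.lung_boundary <- function(x, pixel_size = 1) {
  ellipse_perimeter(x$semiaxes[2], x$semiaxes[3])
}

#' @export
measure_lung_circumference.projection_image <- function(x, pixel_size = 1) {
  measure_lung_circumference(x$pixels > 0,
                             pixel_size = rep_len(x$pixel_size, 2))
}

#' @export
measure_lung_circumference.matrix <- function(x, pixel_size = 1) {
  px <- rep_len(as.numeric(pixel_size), 2)
  fg <- which(x > 0, arr.ind = TRUE)
  if (nrow(fg) < 3) stop("degenerate boundary: fewer than 3 foreground pixels")
  pts <- cbind((fg[, 1] - 0.5) * px[1], (fg[, 2] - 0.5) * px[2])
  hull <- chull(pts)
  if (length(hull) < 3) stop("degenerate boundary: collinear outline")
  hp <- pts[c(hull, hull[1]), ]
  per <- sum(sqrt(rowSums((hp[-1, , drop = FALSE] -
                             hp[-nrow(hp), , drop = FALSE])^2)))
  # the hull of pixel centers sits half a pixel inside the true outline;
  # offsetting a convex contour outward by r adds 2*pi*r to its perimeter
  per + pi * mean(px)
}

# ellipse perimeter by trapezoidal arc-length quadrature
ellipse_perimeter <- function(a, b, n = 20000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  f <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  sum((f[-1] + f[-length(f)]) / 2) * (2 * pi / n)
}

#' Smooth-muscle-cell elongation index
#'
#' How far the muscularized (SMC-covered) vasculature extends from the
#' hilum toward the pleural boundary, as a bounded, scale-free index:
#' for every terminal skeleton node the ratio (distance from hilum to the
#' node) / (distance from hilum to the boundary along the same ray) is
#' computed, and the index is the 90th percentile of these ratios. 0 means
#' all termini sit at the hilum; values near 1 mean termini reach the
#' pleura.
#'
#' @param skeleton a `skeleton_graph` or [vessel_tree()].
#' @param hilum 3D um coordinate of the hilum; defaults to the tree's
#'   metadata when present.
#' @param boundary a [lung_boundary()]; defaults to the tree's metadata.
#'   Must enclose all skeleton points, and the hilum must lie inside.
#' @param prob quantile over terminal-node ratios (default 0.9).
#' @param hilum_exclusion_um termini within this distance of the hilum are
#'   ignored (default 15 um): the vessel mouth at the hilum — including
#'   the root's wall, which physically pokes through the pleural surface
#'   where the vasculature enters — is inflow, not peripheral reach.
#' @return elongation index in \[0, 1\].
#' @export
elongation_index <- function(skeleton, hilum = NULL, boundary = NULL,
                             prob = 0.9, hilum_exclusion_um = 15) {
  stopifnot(inherits(skeleton, "vessel_tree"))
  hilum <- hilum %||% skeleton$metadata$hilum
  boundary <- boundary %||% skeleton$metadata$lung_boundary
  if (is.null(hilum) || is.null(boundary)) {
    stop("`hilum` and `boundary` are required (not found in metadata)")
  }
  if (ellipsoid_frac(hilum, boundary) > 1 + 1e-9) {
    stop("hilum lies outside the boundary ellipsoid")
  }
  deg <- node_degrees(skeleton)
  term <- which(deg <= 1)
  if (length(term) == 0) stop("skeleton has no terminal nodes")
  b <- boundary_at_hilum(boundary, hilum)
  pts <- as.matrix(skeleton$nodes[term, c("z", "y", "x")])
  # the root at the hilum is inflow, not reach; no remaining termini
  # means the muscular network never leaves the mouth: index 0
  d_hilum <- sqrt(rowSums(sweep(pts, 2, as.numeric(hilum))^2))
  keep <- d_hilum > hilum_exclusion_um
  if (!any(keep)) return(0)
  ratios <- vapply(which(keep), function(k) {
    ray_fraction(as.numeric(pts[k, ]), b)
  }, numeric(1))
  # tolerate boundary-hugging wall voxels (vessel walls have thickness;
  # the centerline estimate can sit marginally beyond the ideal surface)
  if (any(ratios > 1.05)) {
    stop("boundary does not enclose all skeleton points")
  }
  quantile(pmin(ratios, 1), prob, names = FALSE, type = 7)
}

# boundary with its hilum replaced (for indices measured from another point)
boundary_at_hilum <- function(boundary, hilum) {
  b <- boundary
  b$hilum <- as.numeric(hilum)
  b
}
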