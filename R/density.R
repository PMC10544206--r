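#' Binarize a 3D volume
#'
#' Binary conversion of a 3D stack, the first step of vessel-density
#' quantification. The default threshold is Otsu's method computed on the
#' histogram of the region of interest (parameter-free, and the chosen
#' threshold is reported alongside the mask for auditability); a fixed
#' threshold may be supplied instead. The comparison is strict
#' (`intensity > threshold`), which makes the all-background case
#' unambiguous.
#'
#' @param volume a [volume_image()] or 3D numeric array.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity cutoff; required iff `method = "fixed"`.
#' @param roi_mask optional logical array restricting the Otsu histogram
#'   (the mask itself is still computed everywhere).
#' @return list with `mask` (logical array), `threshold`, `method`.
#' @export
binarize_volume <- function(volume, method = c("otsu", "fixed"),
                            fixed_threshold = NULL, roi_mask = NULL) {
  method <- match.arg(method)
  vox <- if (inherits(volume, "volume_image")) volume$voxels else volume
  bit_depth <- if (inherits(volume, "volume_image")) volume$bit_depth else 8L
  if (length(vox) == 0) stop("`volume` is empty")
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop("`fixed_threshold` is required when method = \"fixed\"")
    }
    thr <- fixed_threshold
  } else {
    vals <- if (is.null(roi_mask)) as.vector(vox) else vox[roi_mask]
    if (length(vals) == 0) stop("empty region of interest")
    rng <- range(vals)
    if (rng[1] == rng[2]) {
      stop("constant-intensity volume: Otsu threshold is undefined; ",
           "use method = \"fixed\"")
    }
    vmax <- 2^bit_depth - 1
    thr <- EBImage::otsu(matrix(vals / vmax, ncol = 1),
                         range = c(0, 1), levels = 2^bit_depth) * vmax
  }
  list(mask = vox > thr, threshold = thr, method = method)
}

#' Quantify vascular density in a region of interest
#'
#' Counts foreground voxels within the ROI and reports both the density
#' fraction (foreground / ROI voxels, exactly) and the physical foreground
#' volume (voxel count x voxel volume, um^3). When no ROI is given the
#' whole volume is used.
#'
#' @param mask logical array, or the result of [binarize_volume()] (in
#'   which case the reported threshold and method are carried through).
#' @param roi_mask optional logical array of the same shape; must contain
#'   at least one voxel.
#' @param spacing voxel spacing in um (z, y, x).
#' @return An object of class `density_result`: list with `threshold`,
#'   `method`, `foreground_voxels`, `roi_voxels`, `density_fraction`,
#'   `physical_volume` (um^3).
#' @export
vessel_density <- function(mask, roi_mask = NULL, spacing) {
  thr <- NA_real_; method <- NA_character_
  if (is.list(mask) && !is.null(mask$mask)) {
    thr <- mask$threshold; method <- mask$method; mask <- mask$mask
  }
  stopifnot(is.array(mask), length(spacing) == 3L)
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim(mask))
  if (!identical(dim(mask), dim(roi_mask))) {
    stop("`mask` and `roi_mask` must have the same shape")
  }
  nroi <- sum(roi_mask)
  if (nroi == 0) stop("empty region of interest")
  nfg <- sum(mask & roi_mask)
  structure(list(
    threshold = thr,
    method = method,
    foreground_voxels = nfg,
    roi_voxels = nroi,
    density_fraction = nfg / nroi,
    physical_volume = nfg * prod(spacing)
  ), class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "<density_result> %d / %d voxels (fraction %.4f), %.0f um^3%s\n",
    x$foreground_voxels, x$roi_voxels, x$density_fraction,
    x$physical_volume,
    if (!is.na(x$threshold)) sprintf(" [%s threshold %.3g]", x$method,
                                     x$threshold) else ""))
  invisible(x)
}
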