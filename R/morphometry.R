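#' Percent smooth-muscle wall thickness
#'
#' The standard medial-hypertrophy readout for 2D histology:
#' `[(SMC thickness x 2) / vessel diameter] x 100`, with the diameter taken
#' as the external (outer) diameter — the only reading under which a fully
#' muscular vessel tops out at 100%. Invariant to uniform spatial scaling.
#'
#' @param smc_thickness single-side medial thickness, um (>= 0).
#' @param diameter external vessel diameter, um (> 0). A doubled thickness
#'   exceeding the diameter is a geometrically impossible annulus and is an
#'   error.
#' @return percent wall thickness in \[0, 100\]. Vectorized.
#' @examples
#' percent_wall_thickness(5, 50) # 20
#' @export
percent_wall_thickness <- function(smc_thickness, diameter) {
  if (any(diameter <= 0)) stop("`diameter` must be > 0")
  if (any(smc_thickness < 0)) stop("`smc_thickness` must be >= 0")
  if (any(2 * smc_thickness > diameter + 1e-12)) {
    stop("2 x `smc_thickness` exceeds `diameter`: impossible annulus")
  }
  (smc_thickness * 2 / diameter) * 100
}

#' Fulton's right-ventricular-hypertrophy index
#'
#' The weight ratio of the right ventricle to the left ventricle plus
#' interventricular septum, RV / (LV + S). Dimensionless, so any common
#' weight unit (mg, g) gives the same value.
#'
#' @param rv_mg,lv_mg,septum_mg chamber weights, all > 0 (any common
#'   unit). Vectorized.
#' @return RV / (LV + S).
#' @examples
#' fulton_index(25, 80, 20) # 0.25
#' @export
fulton_index <- function(rv_mg, lv_mg, septum_mg) {
  if (any(rv_mg <= 0) || any(lv_mg <= 0) || any(septum_mg <= 0)) {
    stop("all weights must be > 0")
  }
  rv_mg / (lv_mg + septum_mg)
}

#' Classify a vessel by external diameter
#'
#' Two-way stratification of pulmonary vessels into small arteries (at the
#' level of terminal bronchioles) and arterioles (acini / alveolar ducts).
#' Anatomically the classes are defined by the accompanying airway, so the
#' diameter cutoff is an analyst's choice and **must** be supplied — there
#' is deliberately no default. A diameter exactly at the cutoff is a small
#' artery.
#'
#' @param diameter external diameter(s), um, > 0.
#' @param cutoff_um class boundary in um.
#' @return factor with levels `arteriole`, `small_artery`.
#' @export
classify_vessel <- function(diameter, cutoff_um) {
  if (missing(cutoff_um)) stop("`cutoff_um` must be supplied (no default)")
  if (any(diameter <= 0)) stop("`diameter` must be > 0")
  factor(ifelse(diameter >= cutoff_um, "small_artery", "arteriole"),
         levels = c("arteriole", "small_artery"))
}

#' Measure an annular vessel wall in a 2D section image
#'
#' Automates the caliper work of section morphometry: segments the bright
#' wall (Otsu threshold, largest connected component), computes
#' equivalent-circle diameters from the filled (outer) and lumen (inner)
#' areas via d = 2 sqrt(A / pi) — robust to mild non-circularity — takes
#' the wall thickness as (outer - inner) / 2, and applies the percent
#' formula. A filled disk (no lumen) gives inner diameter 0 and 100% wall.
#'
#' @param section_image 2D numeric matrix containing one approximately
#'   annular bright wall.
#' @param pixel_size pixel size in um.
#' @param cutoff_um optional class boundary passed to [classify_vessel()].
#' @param threshold `"otsu"` or a fixed intensity cutoff.
#' @return list of class `morphometry_record`: `external_diameter`,
#'   `internal_diameter`, `smc_thickness` (um), `percent_wall_thickness`,
#'   and `vessel_class` (NA unless `cutoff_um` given).
#' @export
measure_annulus <- function(section_image, pixel_size, cutoff_um = NULL,
                            threshold = "otsu") {
  stopifnot(is.matrix(section_image), pixel_size > 0)
  img <- section_image
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (rng[1] == rng[2]) stop("no annular component found (constant image)")
    EBImage::otsu(img / max(img, 1), range = c(0, 1), levels = 256) *
      max(img, 1)
  } else {
    threshold
  }
  mask <- img > thr
  if (!any(mask)) stop("no annular component found")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  filled <- EBImage::fillHull(comp) > 0
  outer_area <- sum(filled) * pixel_size^2
  inner_area <- (sum(filled) - sum(comp)) * pixel_size^2
  d_out <- 2 * sqrt(outer_area / pi)
  d_in <- 2 * sqrt(inner_area / pi)
  thick <- (d_out - d_in) / 2
  structure(list(
    external_diameter = d_out,
    internal_diameter = d_in,
    smc_thickness = thick,
    percent_wall_thickness = percent_wall_thickness(thick, d_out),
    vessel_class = if (is.null(cutoff_um)) NA else
      as.character(classify_vessel(d_out, cutoff_um)),
    threshold = as.numeric(thr)
  ), class = "morphometry_record")
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf(
    "<morphometry_record> outer %.1f um, wall %.2f um, %.1f%% wall%s\n",
    x$external_diameter, x$smc_thickness, x$percent_wall_thickness,
    if (!is.na(x$vessel_class)) paste0(" [", x$vessel_class, "]") else ""))
  invisible(x)
}

#' Render a synthetic annulus section
#'
#' Test phantom for [measure_annulus()]: a clean annular wall of known
#' outer/inner radius on a dark background, drawn by per-pixel radius test.
#'
#' @param outer_radius,inner_radius radii in um (`inner_radius = 0` gives a
#'   filled disk).
#' @param pixel_size um per pixel.
#' @param size image side in pixels (default fits the annulus with margin).
#' @param fg,bg foreground/background intensities.
#' @return numeric matrix.
#' @export
render_annulus <- function(outer_radius, inner_radius, pixel_size = 0.5,
                           size = NULL, fg = 200, bg = 10) {
  stopifnot(outer_radius > inner_radius, inner_radius >= 0)
  size <- size %||% (2L * ceiling(outer_radius / pixel_size) + 21L)
  ctr <- (size + 1) / 2
  R <- matrix(rep(seq_len(size), size), size)
  C <- matrix(rep(seq_len(size), each = size), size)
  r2 <- ((R - ctr)^2 + (C - ctr)^2) * pixel_size^2
  m <- matrix(bg, size, size)
  m[r2 <= outer_radius^2 & r2 >= inner_radius^2] <- fg
  m
}
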