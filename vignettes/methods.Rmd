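---
title: "Quantifying pulmonary vascular remodeling in 3D: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulmonary vascular remodeling in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmovasc)
```

## The measurement problem

Pulmonary hypertension (PH) remodels the lung vasculature: arterioles
acquire thicker smooth-muscle (SMC) walls, previously non-muscular vessels
muscularize, and — depending on the model — endothelial cells (ECs) sprout
new vessels toward the peripheral lung. In mouse work these changes are
read out from cleared-lung multiphoton stacks (EC lineage labels, α-SMA
wall stain, nuclei), 2D histological sections, and organ weights. This
package implements that entire quantitative readout as reusable, tested
code:

* **3D vessel density** — binarize a stack and count foreground within a
  region of interest;
* **skeleton indices** — centerline skeletonization with neovessel length,
  the *angiogenesis index* (neovessel length / lung circumference) and the
  *SMC elongation index* (how far muscularized vessels reach from the
  hilum toward the pleura);
* **2.5D similarity** — keypoint feature matching between volume renders,
  scored as the mean descriptor distance over matched pairs (lower = more
  similar);
* **2D morphometry** — percent medial wall thickness
  `[(SMC thickness × 2)/vessel diameter] × 100` and Fulton's
  right-ventricular-hypertrophy index `RV/(LV+S)`;
* **group statistics** — one-way ANOVA with Tukey post hoc, pooled
  (Student's) *t* test, and Pearson's χ² on positive/total proportions.

Every stage is exercisable without external data through a ground-truthed
synthetic generator.

## The synthetic generator as study conditions

`generate_vessel_tree()` grows a dichotomously branching, tapering tree
inside an ellipsoidal "lung" from root vessels at a hilum point on its
surface, then applies two remodeling operations whose magnitudes define
the three experimental presets:

| preset | sprouts | elongation | emulates |
|---|---|---|---|
| `normoxia` | 0 | 1.00 | room-air control |
| `suhx` | 4 | 1.08 | VEGFR2-blocked hypoxia (weak angiogenic response) |
| `hx` | 24 | 1.40 | chronic hypoxia (strong sprouting + peripheral elongation) |

The source study reports no absolute sprout counts or lengths per model,
only the qualitative ordering (strong response in hypoxia, near-control
response under VEGFR2 blockade). The preset magnitudes above were chosen
once to encode that ordering at a realistic morphological scale (sprout
lengths 60 ± 15 µm against terminal branch lengths of ~25–40 µm) and are
not revisited; they are explicit parameters, not measurements.

Other fixed choices:

* **Axis order and units.** Everything is z-y-x ordered and measured in
  physical µm with voxel-centered coordinates; with a 13.2 µm z-step
  against 4.54 µm pixels, voxel-unit lengths would be meaningless. The
  three supported voxel geometries (`voxel_geometry()`) are the
  acquisition settings of the emulated microscope: 4.54/13.2, 2.27/6.6 and
  1.13/2.2 µm (xy/z). Defaults use the finest geometry on a
  96 × 224 × 224 grid (≈ 211 × 253 × 253 µm), a desk-scale stand-in for a
  lobe sub-volume.
* **Boundary model.** The pleural boundary is an axis-aligned ellipsoid
  with the hilum on its surface: the simplest region that supports
  "elongation toward the periphery" and a circumference measurement.
* **Sprout lengths** are normal truncated at zero via the inverse-CDF
  construction, so the number of random draws never depends on the draw
  values and seeds reproduce bit-identically. Sprouts grow as polylines
  that bend inward near the pleura, so the drawn length is realized
  exactly and ground-truth totals are exact sums.
* **Elongation** scales terminal tips radially from the hilum; baseline
  growth caps tips at 65% of the hilum-to-boundary ray, so factors up to
  ~1.54 are geometrically valid and anything larger is reported as an
  error rather than clipped.
* **Rasterization** paints each edge as a capsule by per-voxel
  distance-to-segment testing in physical µm (brute force within bounding
  boxes — correctness over speed at 128³-scale volumes). The SMA channel
  paints an annular shell of thickness `wall_thickness_fraction × radius`
  around baseline edges only: neovessels are unmuscularized, matching the
  biology of muscularization as a later remodeling event.
* **Noise** is Poisson shot noise on signal plus constant background and
  Gaussian read noise — the standard fluorescence model; all three are
  exposed and can be zeroed for geometry tests.

What the generator does **not** emulate: optics (no PSF convolution,
depth attenuation or spectral bleed-through), real biological variation in
branching topology, motion/registration artifacts, and staining
heterogeneity. Passing tests therefore demonstrate correctness of the
measurement pipeline on idealized anatomy, not robustness to every
property of real stacks.

## Skeletonization: the numerical choices that matter

`skeletonize_mask()` reduces a binary vessel mask to centerline branches:

1. **Isotropic resampling.** Anisotropic stacks are nearest-neighbor
   resampled to the finest spacing first. Topological thinning yields
   clean centerline *curves* only for objects that are round in voxel
   space; a round vessel at a coarse z-step is plate-like and would thin
   to a medial surface.
2. **Morphological closing (radius 1 voxel).** Voxelized unions of
   near-touching tubes contain 1-voxel background tunnels; each is a
   handle that topology-preserving thinning must braid around, double-
   counting length. Closing seals them.
3. **Topological thinning.** Six-direction border thinning removing
   simple points (one 26-connected foreground component in the
   neighborhood, one adjacent 6-connected background component), with a
   generalized curve-end guard: voxels with ≤ 1 neighbor, or exactly two
   mutually adjacent neighbors, are never deleted. The second clause
   prevents a sequential-recheck cascade from consuming even-symmetric
   rods end-to-end — a real failure mode of naive thinning that surfaced
   on perfectly symmetric phantoms.
4. **Graph extraction and cleanup.** Centerline voxels are linked at
   26-connectivity; branches are maximal paths between endpoints and
   junctions. Terminal spurs shorter than 3 voxels *or* 1.2 × the local
   junction radius are pruned iteratively (thinning sheds spurs up to
   about one tube radius at thick vessels); duplicate rails between the
   same junction pair keep only the shortest; chains through leftover
   degree-2 nodes are fused. Branch polylines get a light 3-point
   moving-average smooth before length measurement, removing the digital
   staircase that otherwise overestimates curve length by 5–8%.

On noise-free phantoms this recovers a 200 µm tube to within one voxel,
Y-junction topology exactly, and whole-tree length to within ~6% of the
generator's ground truth.

**Neovessel classification.** A branch of the post-exposure skeleton is
called a neovessel when under half of its centerline points fall inside
the baseline network dilated by 2 voxels (tolerant to one-voxel jitter
while keeping short sprouts detectable). Because a sprout continues
seamlessly from the baseline tip it grew out of, a neovessel branch
usually carries a short pre-existing stub at its proximal end; only the
centerline portion *outside* the dilated baseline is summed. Summing whole
branches instead inflates recovery error by roughly the terminal-branch /
sprout length ratio (~20% under the default geometry), which is why the
portion-based sum is the package's definition.

**Elongation index.** The upstream definition lives in the authors' prior
work and is not restated in the source; this package defines it concretely
as the 90th percentile over terminal skeleton nodes of
(distance from hilum to node) / (distance from hilum to the boundary along
the same ray). It is bounded in [0, 1], scale-free, 0 when all termini sit
at the hilum and → 1 as termini reach the pleura, and it reproduces the
described phenomenon under the generator's elongation factor.

**Angiogenesis index.** Neovessel *length* (not count) normalized by lung
circumference, following the phrasing "neovessel length … measured"; the
circumference is measured on the mid-axial outline (ellipse arc-length
quadrature for analytic boundaries; convex-hull perimeter of foreground
pixel centers for masks, which avoids pixel-staircase overestimation and
is exact enough for convex pleural outlines — within 2% on circles,
squares and ellipses).

## The 2.5D similarity score

Volumes are compared through 2D renders (maximum-intensity or depth-shaded
projections), the "2.5D" device that makes shape comparison tractable.
The pipeline follows the cited nonlinear-scale-space keypoint framework in
structure, with a behavioral rather than bit-exact contract (determinism,
locality, repeatability — no R binding of the reference implementation
exists):

* **Preprocess**: grayscale (ITU-R BT.601 luma weights by default — the
  source states only "grayscale conversion") and area-weighted resize to
  256 × 256.
* **Detect**: Perona–Malik diffusion (conductance `1/(1+|∇I|²/K²)`, K at
  the 70th gradient percentile) evolved to 3 octaves × 3 sublevels;
  scale-normalized determinant-of-Hessian response; 3×3×3 scale-space
  maxima above a fixed threshold; strongest 400 keypoints.
* **Describe**: upright 486-bit binary descriptor — mean intensity and
  mean x/y derivative over nested 2×2, 3×3, 4×4 cell grids in a 9σ patch,
  all within-grid cell pairs compared per channel.
* **Match**: brute-force Hamming, symmetric mutual-nearest-neighbor by
  default (parameter-free, one-to-one, and symmetric in its arguments —
  which the group comparison requires); Lowe ratio matching available.
* **Score**: the arithmetic mean of matched pair distances. "Distance
  between feature points" is read as *descriptor* (Hamming) distance —
  the standard meaning of match distance, and the only reading under
  which unregistered renders of different animals are comparable. The
  image-space reading is implemented behind
  `similarity_config(score_space = "spatial")`. Unmatched keypoints do
  not enter the score; an empty match set yields a flagged undefined
  score, never 0.

Detector and descriptor parameters are fixed in a versioned default
config so scores are comparable across images and runs — cross-image
comparability is the analysis's whole point.

## Morphometry and statistics

`measure_annulus()` automates section morphometry: Otsu threshold, largest
connected component, fill the lumen, and convert outer/inner areas to
equivalent-circle diameters (`d = 2√(A/π)`, robust to mild
non-circularity). The diameter in the percent-wall formula is the
*external* diameter — the only reading that keeps the percentage ≤ 100 for
a fully muscular vessel. The small-artery/arteriole split is anatomic in
origin (airway landmarks), so `classify_vessel()` deliberately has no
default cutoff: any diameter threshold is an analyst's choice that must be
stated.

The statistics module wraps base R's `aov`/`TukeyHSD`, pooled `t.test` and
`chisq.test` (no continuity correction by default, matching the named
"Pearson's χ²"; the correction is a flag). Tests are two-sided; missing
values are dropped listwise with a logged count. A caveat inherited from
the source design: vessel-level tables ("n = 16 vessels from 4 mice")
treat vessels as independent units; the module tests whatever unit the
table provides.

## Problem sizes and determinism

Defaults keep everything desk-scale: 96 × 224 × 224 volumes (≈ 5M voxels,
a few seconds to rasterize and skeletonize each), 256² renders with a few
hundred keypoints (well under a second per comparison), and Monte-Carlo
calibration at 2,000 replicates. All randomness flows through explicit
integer seeds; generator outputs are bit-identical under identical
parameters, and package functions restore the caller's RNG state.

## Known limitations

* Skeleton branch tips stop roughly one tube radius short of blunt vessel
  ends (endpoint erosion inherent to thinning); tree-level totals stay
  within a few percent.
* The neovessel classifier assumes pre-aligned baseline and post volumes;
  there is no registration step (the generator guarantees alignment).
* The similarity detector is not rotation invariant (upright
  descriptors); large rotations read as dissimilarity, which is the
  desired behavior for the graded-perturbation harness but means renders
  should share an orientation convention.
* Density quantification is plain binarization — no vesselness filtering,
  matching the source procedure.
* The voxel-counting reading of "integral of the area of interest" is
  used for density; per-slice area summation is proportional under fixed
  spacing.
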