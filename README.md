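# pulmovasc

Quantitative 3D image analysis of pulmonary vascular remodeling in mouse
models of pulmonary hypertension (PH).

Chronic hypoxia drives an angiogenic response in the mouse lung —
endothelial sprouting and elongation of muscularized vessels toward the
pleura — while severer, VEGFR2-blocked models (SU5416 + hypoxia) largely
lack it. Reading these changes out of cleared-lung multiphoton stacks,
histological sections and organ weights requires a chain of measurements
that are usually done by hand. `pulmovasc` implements that chain as
tested, reusable R code:

* **Synthetic data** (`synth_params()`, `generate_vessel_tree()`,
  `rasterize_tree()`, `render_projection()`, `perturb_projection()`,
  `simulate_group_table()`): a ground-truthed generator for anisotropic
  3D stacks of a branching, tapering vascular tree with hypoxia-style
  neovessel sprouts, an α-SMA wall layer, and a realistic noise model;
  presets `normoxia` / `suhx` / `hx` encode the three exposure groups.
* **Vessel density** (`binarize_volume()`, `vessel_density()`): binary
  conversion (Otsu or fixed threshold) and density fraction / physical
  volume within a region of interest.
* **Skeleton indices** (`skeletonize_mask()`, `neovessel_length()`,
  `angiogenesis_index()`, `elongation_index()`,
  `measure_lung_circumference()`): topological centerline extraction in
  physical µm, neovessel length against a baseline network, the
  angiogenesis index
  `total neovessel length / lung circumference`, and the SMC elongation
  index (90th percentile of terminal radial reach from the hilum,
  in [0, 1]).
* **2.5D similarity** (`similarity_score()`, `detect_and_describe()`,
  `match_features()`): nonlinear-scale-space keypoints with binary
  descriptors on 256×256 grayscale renders, matched by Hamming distance
  with symmetric mutual nearest neighbors; the similarity score is the
  mean distance over matched pairs — **lower = more similar**.
* **Morphometry** (`measure_annulus()`, `percent_wall_thickness()`,
  `classify_vessel()`, `fulton_index()`): percent medial wall thickness
  `[(SMC thickness × 2)/vessel diameter] × 100` and Fulton's index
  `RV/(LV + S)`.
* **Statistics** (`one_way_anova_tukey()`, `two_sample_t()`,
  `chi2_proportions()`): the group comparisons used throughout such
  studies, with a simulation harness for calibration.

## Worked example

Generate the hypoxia and normoxia presets, measure the angiogenic
response, and compare renders:

```r
library(pulmovasc)

nx <- preset_params("normoxia", seed = 1)
hx <- preset_params("hx",       seed = 1)   # same baseline tree, + remodeling

tree_nx <- generate_vessel_tree(nx)
tree_hx <- generate_vessel_tree(hx)
vol_nx  <- rasterize_tree(tree_nx, nx, "EC")
vol_hx  <- rasterize_tree(tree_hx, hx, "EC")

# angiogenesis index of the hypoxic lung against its own baseline
res <- measure_angiogenesis(vol_hx, vol_nx, tree_hx$metadata$lung_boundary)
res
#> <index_result> angiogenesis index 3.7911 (neovessel 2713.2 um / circumference 715.7 um)

# 2.5D similarity of the renders (lower = more similar)
s <- similarity_score(render_projection(vol_hx), render_projection(vol_nx))
s
#> <match_result> 100 matches (400 vs 387 keypoints), similarity score 50.400

fulton_index(25, 80, 20)        # right-ventricular hypertrophy, RV/(LV+S)
#> [1] 0.25
percent_wall_thickness(5, 50)   # medial wall thickness, %
#> [1] 20
```

The hypoxic preset carries 24 sprouts plus tip elongation, so its
neovessel length (and index) is large and its render sits far from the
normoxia render in descriptor space; the `suhx` preset (4 sprouts) lands
between, scoring *closer* to normoxia than `hx` does — the direction of
effect the 3D imaging analysis is designed to detect.

See `vignettes/methods.Rmd` for the model, parameter and design
discussion.

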