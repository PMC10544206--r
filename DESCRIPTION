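Package: pulmovasc
Title: Quantitative 3D Image Analysis of Pulmonary Vascular Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pulmonary vascular remodeling in mouse
    models of pulmonary hypertension from 3D fluorescence microscopy.
    Provides a ground-truthed synthetic generator for anisotropic vascular
    image stacks (branching, tapering trees with hypoxia-style neovessel
    sprouts and a smooth-muscle wall layer), binarization-based 3D vessel
    density, centerline skeletonization with neovessel-length, angiogenesis
    and smooth-muscle-cell elongation indices, a 2.5D keypoint
    feature-matching similarity score between volume renderings, 2D vessel
    wall morphometry with Fulton's right-ventricular-hypertrophy index, and
    the group-comparison statistics (one-way ANOVA with Tukey post hoc,
    Student's t test, Pearson's chi-squared on proportions) used to compare
    experimental groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tiff,
    png,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
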