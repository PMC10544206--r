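# Shared fixtures, built in code and memoized for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# noise-free generator parameters (geometry checks need exact voxels)
quiet_params <- function(...) {
  synth_params(..., background_level = 0, shot_noise_scale = 0,
               gaussian_noise_sd = 0)
}

# a hand-built straight axis-aligned tube as a vessel_tree + params
tube_fixture <- function(length_um = 200, radius_um = 4,
                         shape = c(40L, 40L, 120L), spacing = c(2, 2, 2)) {
  ext <- shape * spacing
  a <- c(ext[1] / 2, ext[2] / 2, (ext[3] - length_um) / 2)
  b <- a + c(0, 0, length_um)
  nodes <- data.frame(id = 1:2, z = c(a[1], b[1]), y = c(a[2], b[2]),
                      x = c(a[3], b[3]), radius = radius_um)
  edges <- data.frame(from = 1L, to = 2L, label = "baseline",
                      length = length_um, radius = radius_um)
  list(tree = vessel_tree(nodes, edges),
       params = quiet_params(volume_shape = shape, spacing = spacing),
       length = length_um, radius = radius_um)
}

# Y-shaped tree: one bifurcation, three tips
y_fixture <- function() {
  c0 <- c(40, 40, 40)
  c1 <- c0 + c(0, 0, 80)
  c2 <- c1 + c(0, 40, 40)
  c3 <- c1 + c(0, -40, 40)
  pts <- rbind(c0, c1, c2, c3)
  eln <- function(a, b) sqrt(sum((a - b)^2))
  nodes <- data.frame(id = 1:4, z = pts[, 1], y = pts[, 2], x = pts[, 3],
                      radius = 4)
  edges <- data.frame(from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                      label = "baseline",
                      length = c(eln(c0, c1), eln(c1, c2), eln(c1, c3)),
                      radius = 4)
  list(tree = vessel_tree(nodes, edges),
       params = quiet_params(volume_shape = c(40L, 60L, 90L),
                             spacing = c(2, 2, 2)))
}

# noise-free EC mask of the seed-7 tree with the given sprout count
quiet_mask <- function(n_sprouts, seed = 7) {
  memo(paste0("mask_", seed, "_", n_sprouts), {
    p <- quiet_params(seed = seed, n_sprouts = n_sprouts)
    tree <- generate_vessel_tree(p)
    vol <- rasterize_tree(tree, p, "EC")
    list(params = p, tree = tree,
         mask = binarize_volume(vol, "fixed", fixed_threshold = 100)$mask)
  })
}

quiet_skeleton <- function(n_sprouts, seed = 7) {
  memo(paste0("skel_", seed, "_", n_sprouts), {
    f <- quiet_mask(n_sprouts, seed)
    skeletonize_mask(f$mask, f$params$spacing)
  })
}

# full preset pipeline at default (noisy) conditions, shared seed
preset_fixture <- function(preset, seed = 1) {
  memo(paste0("preset_", preset, "_", seed), {
    p <- preset_params(preset, seed = seed)
    tree <- generate_vessel_tree(p)
    vol <- rasterize_tree(tree, p, "EC")
    list(params = p, tree = tree, vol = vol,
         proj = render_projection(vol))
  })
}

# small noisy projection for detector tests (cheap: 1/8-size volume)
small_projection <- function(seed = 3) {
  memo(paste0("proj_", seed), {
    p <- synth_params(seed = seed, volume_shape = c(48L, 112L, 112L))
    render_projection(rasterize_tree(generate_vessel_tree(p), p, "EC"))
  })
}
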