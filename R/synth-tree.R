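#' Generate a ground-truthed synthetic vascular tree
#'
#' Grows a branching, tapering vascular tree inside an ellipsoidal lung
#' boundary, starting from root vessels at the hilum. Three remodeling
#' features of hypoxic pulmonary hypertension are emulated and fully
#' recorded as ground truth:
#'
#' * **sprouting**: `n_sprouts` neovessel sprouts are appended to terminal
#'   baseline nodes, with lengths drawn from a normal distribution truncated
#'   at zero (inverse-CDF truncation, so the draw count is deterministic);
#'   sprouts grow as polylines that bend away from the pleural boundary, so
#'   the drawn length is always realized exactly;
#' * **elongation**: terminal baseline tips are scaled radially from the
#'   hilum by `elongation_factor`; a factor that would push any tip outside
#'   the boundary is an error, never a silent clip;
#' * **tapering**: child radius = parent radius x `taper_ratio`, so radii
#'   are non-increasing from root to tip.
#'
#' Total baseline and neovessel lengths are recorded in `metadata` and are
#' exact sums of the emitted edge lengths.
#'
#' @param params a [synth_params()] object.
#' @return A [vessel_tree()] with `metadata` containing `lung_boundary`
#'   (a [lung_boundary()] descriptor), `hilum`, `total_baseline_length` and
#'   `total_neovessel_length` (um).
#' @examples
#' tree <- generate_vessel_tree(synth_params(seed = 7, n_sprouts = 5))
#' tree$metadata$total_neovessel_length
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  extent <- params$volume_shape * params$spacing
  center <- extent / 2
  semi <- 0.45 * extent
  hilum <- center
  hilum[3] <- center[3] - semi[3]
  boundary <- lung_boundary(center, semi, hilum)

  # baseline tips are capped at this fraction of the hilum-to-boundary ray;
  # elongation then has headroom up to 1/cap before breaching the pleura
  tip_cap <- 0.65
  if (params$elongation_factor > 1 / tip_cap) {
    stop(sprintf(
      "elongation_factor %.3g would push tips outside the lung boundary (max %.3g)",
      params$elongation_factor, 1 / tip_cap))
  }

  with_seed(params$seed, {
    nodes <- data.frame(id = 1L, z = hilum[1], y = hilum[2], x = hilum[3],
                        radius = params$root_radius)
    edges <- data.frame(from = integer(), to = integer(),
                        label = character(), length = numeric(),
                        radius = numeric())
    polylines <- list()
    next_id <- 2L

    add_node <- function(p, r) {
      id <- next_id
      next_id <<- next_id + 1L
      nodes[nrow(nodes) + 1L, ] <<- list(id, p[1], p[2], p[3], r)
      id
    }
    add_edge <- function(from, to, label, pl, radius) {
      len <- sum(sqrt(rowSums((pl[-1, , drop = FALSE] -
                                 pl[-nrow(pl), , drop = FALSE])^2)))
      edges[nrow(edges) + 1L, ] <<- list(from, to, label, len, radius)
      polylines[[length(polylines) + 1L]] <<- pl
    }

    # shorten a straight segment from p along dir so its endpoint stays at
    # ray fraction <= cap; returns the achievable length (possibly 0)
    clip_length <- function(p, dir, len, cap) {
      q <- p + len * dir
      if (ray_fraction(q, boundary) <= cap) return(len)
      f <- function(t) ray_fraction(p + t * len * dir, boundary) - cap
      if (f(0) >= 0) return(0)
      stats::uniroot(f, c(0, 1), tol = 1e-8)$root * len
    }

    spread <- params$branch_angle_spread * pi / 180
    seg0 <- 0.42 * min(semi)

    # frontier rows: node id, direction, radius, segment length
    frontier <- list()
    for (k in seq_len(params$n_root_vessels)) {
      dir <- tilt_dir(c(0, 0, 1), abs(rnorm(1, 0, spread / 4)),
                      runif(1, 0, 2 * pi))
      frontier[[k]] <- list(node = 1L, dir = dir, radius = params$root_radius,
                            seglen = seg0)
    }

    for (gen in seq_len(params$branch_generations)) {
      new_frontier <- list()
      for (br in frontier) {
        p <- as.numeric(nodes[match(br$node, nodes$id), c("z", "y", "x")])
        phi <- runif(1, 0, 2 * pi)
        for (side in c(0, pi)) {
          theta <- (spread / 2) * runif(1, 0.5, 1)
          dir <- tilt_dir(br$dir, theta, phi + side)
          r <- br$radius * if (gen == 1) 1 else params$taper_ratio
          len <- clip_length(p, dir, br$seglen, tip_cap)
          if (len < 2) next
          q <- p + len * dir
          id <- add_node(q, r)
          add_edge(br$node, id, "baseline", rbind(p, q), r)
          new_frontier[[length(new_frontier) + 1L]] <-
            list(node = id, dir = dir, radius = r, seglen = br$seglen * 0.85)
        }
      }
      if (length(new_frontier) == 0) break
      frontier <- new_frontier
    }

    tree0 <- list(nodes = nodes, edges = edges)
    deg <- table(factor(c(edges$from, edges$to), levels = nodes$id))
    tips <- nodes$id[deg == 1 & nodes$id != 1L]

    # elongation: scale terminal tips radially from the hilum
    if (params$elongation_factor > 1) {
      bad <- integer()
      for (id in tips) {
        i <- match(id, nodes$id)
        p <- as.numeric(nodes[i, c("z", "y", "x")])
        q <- hilum + params$elongation_factor * (p - hilum)
        if (ellipsoid_frac(q, boundary) > 1) {
          bad <- c(bad, id)
          next
        }
        nodes[i, c("z", "y", "x")] <- as.list(q)
        j <- which(edges$to == id | edges$from == id)[1]
        pl <- polylines[[j]]
        if (edges$to[j] == id) pl[nrow(pl), ] <- q else pl[1, ] <- q
        polylines[[j]] <- pl
        edges$length[j] <- sum(sqrt(rowSums(
          (pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2)))
      }
      if (length(bad)) {
        stop("elongation_factor pushes tip node(s) ",
             paste(bad, collapse = ", "), " outside the lung boundary")
      }
    }

    # neovessel sprouts on terminal baseline nodes
    if (params$n_sprouts > 0) {
      attach_ids <- tips[sample.int(length(tips), params$n_sprouts,
                                    replace = TRUE)]
      u <- runif(params$n_sprouts)
      p0 <- stats::pnorm(0, params$sprout_length_mean, params$sprout_length_sd)
      lens <- if (params$sprout_length_sd == 0) {
        rep(params$sprout_length_mean, params$n_sprouts)
      } else {
        stats::qnorm(p0 + u * (1 - p0), params$sprout_length_mean,
                     params$sprout_length_sd)
      }
      for (k in seq_len(params$n_sprouts)) {
        i <- match(attach_ids[k], nodes$id)
        p <- as.numeric(nodes[i, c("z", "y", "x")])
        r <- 0.6 * nodes$radius[i]
        dir <- tilt_dir(unit(p - hilum), abs(rnorm(1, 0, 25 * pi / 180)),
                        runif(1, 0, 2 * pi))
        pl <- sprout_walk(p, dir, lens[k], boundary)
        id <- add_node(pl[nrow(pl), ], r)
        add_edge(attach_ids[k], id, "neovessel", pl, r)
      }
    }

    metadata <- list(
      lung_boundary = boundary,
      hilum = hilum,
      total_baseline_length = sum(edges$length[edges$label == "baseline"]),
      total_neovessel_length = sum(edges$length[edges$label == "neovessel"])
    )
    vessel_tree(nodes, edges, polylines, metadata)
  })
}

# grow a sprout polyline of exactly `len` um from p along dir, bending
# toward the interior whenever a step would cross 97% of the hilum ray
sprout_walk <- function(p, dir, len, boundary, step = 8) {
  pts <- matrix(p, 1, 3)
  remaining <- len
  while (remaining > 1e-9) {
    s <- min(step, remaining)
    for (tries in 1:12) {
      q <- p + s * dir
      if (ray_fraction(q, boundary) <= 0.97) break
      dir <- unit(0.6 * dir + 0.4 * unit(boundary$center - p))
    }
    q <- p + s * dir
    if (ray_fraction(q, boundary) > 0.999) {
      # pathological corner: head straight for the center
      dir <- unit(boundary$center - p)
      q <- p + s * dir
    }
    pts <- rbind(pts, q)
    p <- q
    remaining <- remaining - s
  }
  dimnames(pts) <- NULL
  pts
}

#' Study-condition presets for the synthetic generator
#'
#' The three exposure groups being emulated differ only in neovessel burden
#' and tip elongation, mirroring the biology: normoxia (`"normoxia"`) has no
#' sprouting, chronic hypoxia (`"hx"`) shows strong sprouting and peripheral
#' elongation, and SU5416 + hypoxia (`"suhx"`) — the severer, VEGFR2-blocked
#' model — shows only a weak angiogenic response, closer to normoxia.
#'
#' @param preset one of `"normoxia"`, `"hx"`, `"suhx"`.
#' @param seed generator seed (shared across presets so that the baseline
#'   network is identical and only the remodeling differs).
#' @param ... overrides passed on to [synth_params()].
#' @return A [synth_params()] object.
#' @export
preset_params <- function(preset = c("normoxia", "hx", "suhx"), seed = 1L,
                          ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    normoxia = list(n_sprouts = 0L, elongation_factor = 1),
    hx = list(n_sprouts = 24L, elongation_factor = 1.4),
    suhx = list(n_sprouts = 4L, elongation_factor = 1.08)
  )
  do.call(synth_params, c(list(seed = seed), cfg, list(...)))
}
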