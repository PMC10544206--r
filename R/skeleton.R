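#' Extract a centerline skeleton graph from a binary vessel mask
#'
#' Topologically thins the mask to 1-voxel-wide 26-connected centerlines,
#' links centerline voxels into a geometric graph and measures branch
#' lengths in physical um. Interior degree-2 voxels are absorbed into
#' branch polylines, so branches are maximal paths between endpoints and
#' junctions. A per-branch mean radius is estimated from the Euclidean
#' distance transform of the mask.
#'
#' Anisotropic stacks are first resampled (nearest neighbor) onto an
#' isotropic grid at the finest spacing: topological thinning only yields
#' clean centerline *curves* for tubes that are round in voxel space — a
#' round vessel sampled at a coarse z-step is plate-like and would thin to
#' a medial surface instead. All lengths are physical um either way.
#'
#' Small connected components (thinning debris) and short terminal spurs —
#' a standard artifact of 3D thinning at tube surfaces — are removed.
#'
#' @param mask logical/integer 3D array, or the result of
#'   [binarize_volume()]; must contain at least one foreground voxel.
#' @param spacing voxel spacing in um (z, y, x).
#' @param close_radius morphological closing radius (voxels, Euclidean)
#'   applied before thinning. Voxelized unions of near-touching tubes are
#'   riddled with 1-voxel background tunnels; each tunnel is a handle that
#'   the (topology-preserving) thinning must braid around, double-counting
#'   length. Closing seals them. 0 disables.
#' @param min_component_voxels connected components (26-connectivity) with
#'   fewer skeleton voxels than this are dropped.
#' @param prune_spur_voxels terminal branches with at most this many
#'   centerline voxels hanging off a junction are removed as thinning
#'   spurs.
#' @param prune_radius_factor terminal branches shorter than this multiple
#'   of the junction's local radius are also removed: thinning of a thick
#'   tube sheds spurs up to about one tube radius long, so the filter must
#'   scale with vessel caliber.
#' @param hilum optional 3D um coordinate; when given, nodes carry a
#'   `branch_order` (graph distance from the node nearest the hilum).
#' @return A `skeleton_graph` (also a [vessel_tree()]): nodes with um
#'   coordinates and local radius, edges with polyline `length` (um),
#'   `mean_radius` and `n_points`, and `metadata$total_length`.
#' @export
skeletonize_mask <- function(mask, spacing, close_radius = 1,
                             min_component_voxels = 4L,
                             prune_spur_voxels = 3L,
                             prune_radius_factor = 1.2, hilum = NULL) {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  stopifnot(is.array(mask), length(dim(mask)) == 3L, length(spacing) == 3L)
  if (!any(mask)) stop("`mask` is empty")
  spacing <- as.numeric(spacing)
  if (max(spacing) / min(spacing) > 1.05) {
    iso <- min(spacing)
    rs <- resample_nn(mask != 0, spacing, iso)
    mask <- rs
    spacing <- rep(iso, 3)
  }
  if (close_radius > 0) mask <- close_binary(mask != 0, close_radius)
  dims <- dim(mask)
  thin <- cpp_thin3d(as.integer(mask != 0), as.integer(dims))
  edt <- cpp_edt3d(as.integer(mask != 0), as.integer(dims),
                   as.numeric(spacing))
  vox <- which(thin == 1L)
  g <- skel_graph(vox, dims, spacing, edt, min_component_voxels)
  # prune spurs iteratively (each rebuild re-merges degree-2 nodes and can
  # expose a fresh layer of spurs at thick junction clusters)
  for (pass in seq_len(10L)) {
    if (prune_spur_voxels <= 0 || nrow(g$edges) <= 1) break
    deg <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes$id))
    drop <- logical(nrow(g$edges))
    rm_vox <- integer()
    for (i in seq_len(nrow(g$edges))) {
      e <- g$edges[i, ]
      d_from <- deg[[as.character(e$from)]]
      d_to <- deg[[as.character(e$to)]]
      tip <- if (d_from == 1 && d_to >= 3) e$from
             else if (d_to == 1 && d_from >= 3) e$to else NA
      if (is.na(tip)) next
      junction <- if (tip == e$from) e$to else e$from
      jr <- g$nodes$radius[match(junction, g$nodes$id)]
      if (e$n_points <= prune_spur_voxels + 1L ||
          e$length < prune_radius_factor * jr) {
        drop[i] <- TRUE
        pathv <- g$edge_vox[[i]]
        rm_vox <- c(rm_vox, setdiff(pathv, g$node_vox[
          match(junction, g$nodes$id)]))
      }
    }
    if (!any(drop)) break
    vox <- setdiff(vox, rm_vox)
    g <- skel_graph(vox, dims, spacing, edt, min_component_voxels)
  }
  # drop duplicate rails between the same junction pair (tiny handles that
  # survived closing), then fuse chains through the degree-2 nodes left by
  # the removals
  g <- dedupe_edges(g)
  g <- merge_degree2(g)

  nodes <- g$nodes
  keep_n <- nodes$id %in% c(g$edges$from, g$edges$to)
  if (any(keep_n)) nodes <- nodes[keep_n, , drop = FALSE]
  rownames(nodes) <- NULL
  if (!is.null(hilum)) {
    nodes$branch_order <- branch_order_from(nodes, g$edges, hilum)
  }
  metadata <- list(total_length = sum(g$edges$length), spacing = spacing)
  tree <- vessel_tree(nodes, g$edges[, c("from", "to", "label", "length",
                                         "radius")],
                      g$polylines, metadata)
  tree$edges$mean_radius <- g$edges$mean_radius
  tree$edges$n_points <- g$edges$n_points
  class(tree) <- c("skeleton_graph", class(tree))
  tree
}

# keep only the shortest edge among parallel edges joining the same pair
dedupe_edges <- function(g) {
  key <- paste(pmin(g$edges$from, g$edges$to),
               pmax(g$edges$from, g$edges$to))
  keep <- rep(TRUE, nrow(g$edges))
  for (k in unique(key[duplicated(key)])) {
    w <- which(key == k)
    keep[w[-which.min(g$edges$length[w])]] <- FALSE
  }
  g$edges <- g$edges[keep, , drop = FALSE]
  g$polylines <- g$polylines[keep]
  rownames(g$edges) <- NULL
  g
}

# fuse the two edges incident to each degree-2 node into one branch
merge_degree2 <- function(g) {
  repeat {
    deg <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes$id))
    selfs <- g$edges$from[g$edges$from == g$edges$to]
    cand <- g$nodes$id[deg == 2 & !g$nodes$id %in% selfs]
    if (length(cand) == 0) break
    id <- cand[1]
    ei <- which(g$edges$from == id | g$edges$to == id)
    if (length(ei) != 2) break # safeguard (should not happen)
    # orient each polyline to run towards `id`, then splice
    orient <- function(i) {
      pl <- g$polylines[[i]]
      if (g$edges$to[i] == id) list(pl = pl, far = g$edges$from[i])
      else list(pl = pl[rev(seq_len(nrow(pl))), , drop = FALSE],
                far = g$edges$to[i])
    }
    o1 <- orient(ei[1]); o2 <- orient(ei[2])
    pl <- rbind(o1$pl, o2$pl[rev(seq_len(nrow(o2$pl)))[-1], , drop = FALSE])
    e <- g$edges[ei[1], ]
    e$from <- o1$far; e$to <- o2$far
    e$length <- g$edges$length[ei[1]] + g$edges$length[ei[2]]
    np <- g$edges$n_points[ei]
    e$mean_radius <- sum(g$edges$mean_radius[ei] * np) / sum(np)
    e$n_points <- sum(np) - 1L
    g$edges <- g$edges[-ei, , drop = FALSE]
    g$polylines <- g$polylines[-ei]
    g$edges <- rbind(g$edges, e)
    rownames(g$edges) <- NULL
    g$polylines[[length(g$polylines) + 1L]] <- pl
  }
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d branches, total length %.1f um\n",
              nrow(x$nodes), nrow(x$edges), x$metadata$total_length))
  invisible(x)
}

# Build the simplified geometric graph from skeleton voxel linear indices.
skel_graph <- function(vox, dims, spacing, edt, min_component_voxels) {
  vox <- sort(vox)
  n <- length(vox)
  if (n == 0) stop("skeleton is empty after filtering")
  idx <- arrayInd(vox, dims) # z, y, x voxel indices
  nz <- dims[1]; ny <- dims[2]

  # 26-neighborhood adjacency as an n x 26 matrix of row numbers
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  nb <- matrix(NA_integer_, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    zz <- idx[, 1] + offs$dz[k]
    yy <- idx[, 2] + offs$dy[k]
    xx <- idx[, 3] + offs$dx[k]
    ok <- zz >= 1 & zz <= dims[1] & yy >= 1 & yy <= dims[2] &
      xx >= 1 & xx <= dims[3]
    lin <- (zz - 1L) + nz * (yy - 1L) + nz * ny * (xx - 1L) + 1L
    m <- match(lin, vox)
    m[!ok] <- NA_integer_
    nb[, k] <- m
  }
  deg <- rowSums(!is.na(nb))

  # connected components (BFS), drop tiny ones
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      vs <- nb[u, ]
      vs <- vs[!is.na(vs)]
      new <- vs[comp[vs] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  keep <- comp %in% which(tabulate(comp) >= min_component_voxels)
  if (!any(keep)) keep <- comp == comp[which.max(deg)] # keep something
  if (!all(keep)) {
    return(skel_graph(vox[keep], dims, spacing, edt,
                      min_component_voxels = 1L))
  }

  # node voxels: degree != 2, plus one anchor per pure cycle
  is_node <- deg != 2
  for (cid in seq_len(cur)) {
    rows <- which(comp == cid)
    if (!any(is_node[rows])) is_node[rows[1]] <- TRUE
  }
  node_rows <- which(is_node)
  node_id <- integer(n)
  node_id[node_rows] <- seq_along(node_rows)

  coords_um <- sweep(idx - 0.5, 2, spacing, `*`)
  nodes <- data.frame(id = seq_along(node_rows),
                      z = coords_um[node_rows, 1],
                      y = coords_um[node_rows, 2],
                      x = coords_um[node_rows, 3],
                      radius = edt[vox[node_rows]])

  node_vox_map <- vox[node_rows]

  edges <- data.frame(from = integer(), to = integer(), label = character(),
                      length = numeric(), radius = numeric(),
                      mean_radius = numeric(), n_points = integer())
  polylines <- list()
  edge_vox <- list()
  used <- new.env(hash = TRUE)

  for (u in node_rows) {
    for (v in nb[u, ]) {
      if (is.na(v)) next
      key <- paste(u, v)
      if (!is.null(used[[key]])) next
      # walk from u through v until the next node voxel
      path <- c(u, v)
      prev <- u
      curv <- v
      while (!is_node[curv]) {
        nxt <- nb[curv, ]
        nxt <- nxt[!is.na(nxt) & nxt != prev]
        # prefer non-path voxels (guards against revisiting in thick spots)
        nxt <- nxt[!nxt %in% path[-length(path)]]
        if (length(nxt) == 0) { is_node[curv] <- TRUE; break }
        prev <- curv
        curv <- nxt[1]
        path <- c(path, curv)
      }
      used[[key]] <- TRUE
      used[[paste(path[length(path)], path[length(path) - 1L])]] <- TRUE
      endv <- path[length(path)]
      if (!node_id[endv]) { # promoted mid-walk
        node_id[endv] <- max(node_id) + 1L
        nodes[nrow(nodes) + 1L, ] <- list(node_id[endv],
                                          coords_um[endv, 1],
                                          coords_um[endv, 2],
                                          coords_um[endv, 3],
                                          edt[vox[endv]])
        node_vox_map <- c(node_vox_map, vox[endv])
      }
      # a light moving-average smooth of the voxel chain removes the
      # digital staircase that otherwise overestimates curve length
      pl <- smooth_polyline(unname(coords_um[path, , drop = FALSE]))
      len <- sum(sqrt(rowSums((pl[-1, , drop = FALSE] -
                                 pl[-nrow(pl), , drop = FALSE])^2)))
      edges[nrow(edges) + 1L, ] <- list(
        node_id[u], node_id[endv], "unclassified", len,
        mean(edt[vox[path]]), mean(edt[vox[path]]), length(path))
      polylines[[length(polylines) + 1L]] <- pl
      edge_vox[[length(edge_vox) + 1L]] <- vox[path]
    }
  }

  list(nodes = nodes, edges = edges, polylines = polylines,
       edge_vox = edge_vox, node_vox = node_vox_map)
}

# morphological closing (Euclidean, voxel units) via two distance passes
close_binary <- function(mask, radius) {
  dims <- dim(mask)
  d_to_fg <- cpp_edt3d(as.integer(!mask), as.integer(dims), c(1, 1, 1))
  dil <- d_to_fg <= radius
  d_to_bg <- cpp_edt3d(as.integer(dil), as.integer(dims), c(1, 1, 1))
  d_to_bg > radius
}

# nearest-neighbor resample of a binary volume onto an isotropic grid,
# preserving physical extent
resample_nn <- function(mask, spacing, iso) {
  dims <- dim(mask)
  ax <- lapply(1:3, function(a) {
    n_new <- max(1L, as.integer(round(dims[a] * spacing[a] / iso)))
    pmin(pmax(as.integer(round((seq_len(n_new) - 0.5) * iso / spacing[a] +
                                 0.5)), 1L), dims[a])
  })
  mask[ax[[1]], ax[[2]], ax[[3]]]
}

# 3-point moving average of interior polyline points, endpoints fixed
smooth_polyline <- function(pl) {
  n <- nrow(pl)
  if (n < 3) return(pl)
  out <- pl
  out[2:(n - 1), ] <- (pl[1:(n - 2), ] + pl[2:(n - 1), ] + pl[3:n, ]) / 3
  out
}

# breadth-first branch order from the node nearest the hilum
branch_order_from <- function(nodes, edges, hilum) {
  d <- sqrt((nodes$z - hilum[1])^2 + (nodes$y - hilum[2])^2 +
              (nodes$x - hilum[3])^2)
  root <- which.min(d)
  ord <- rep(NA_integer_, nrow(nodes))
  ord[root] <- 0L
  queue <- root
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    uid <- nodes$id[u]
    adj <- c(edges$to[edges$from == uid], edges$from[edges$to == uid])
    for (vid in adj) {
      v <- match(vid, nodes$id)
      if (is.na(ord[v])) {
        ord[v] <- ord[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  ord
}
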