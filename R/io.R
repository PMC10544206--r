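#' Read and write volumes, trees and projections
#'
#' Volumes are stored as multi-page TIFF (one file per channel, pages along
#' z) plus a JSON sidecar carrying the um spacing, channel, bit depth and —
#' for synthetic volumes — the full generator parameters. Vessel trees are
#' stored as a CSV segment list (one row per polyline segment, with node
#' ids, um coordinates, radius, label and segment length) plus JSON
#' metadata. Projections are stored as 8-bit PNG plus a JSON sidecar.
#'
#' @param volume a [volume_image()].
#' @param path output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param params optional [synth_params()] recorded in the sidecar.
#' @return `write_*` return `path` invisibly; `read_*` return the restored
#'   object.
#' @name pulmovasc-io
NULL

#' @rdname pulmovasc-io
#' @export
write_volume <- function(volume, path, params = NULL) {
  stopifnot(inherits(volume, "volume_image"))
  vmax <- 2^volume$bit_depth - 1
  pages <- lapply(seq_len(dim(volume$voxels)[1]), function(z) {
    volume$voxels[z, , ] / vmax
  })
  tiff::writeTIFF(pages, path, bits.per.sample = volume$bit_depth)
  side <- list(spacing = volume$spacing, channel = volume$channel,
               bit_depth = volume$bit_depth)
  if (!is.null(params)) side$params <- unclass(params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pulmovasc-io
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  vmax <- 2^side$bit_depth - 1
  vox <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (z in seq_along(pages)) vox[z, , ] <- round(pages[[z]] * vmax)
  volume_image(vox, side$spacing, side$channel, side$bit_depth)
}

#' @rdname pulmovasc-io
#' @param tree a [vessel_tree()].
#' @export
write_vessel_tree <- function(tree, path) {
  stopifnot(inherits(tree, "vessel_tree"))
  rows <- lapply(seq_len(nrow(tree$edges)), function(i) {
    e <- tree$edges[i, ]
    pl <- edge_polyline(tree, i)
    ns <- nrow(pl) - 1L
    seg_len <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                               pl[-nrow(pl), , drop = FALSE])^2))
    data.frame(edge_id = i, seg = seq_len(ns),
               from_id = c(e$from, rep(NA, ns - 1L)),
               to_id = c(rep(NA, ns - 1L), e$to),
               z1 = pl[-nrow(pl), 1], y1 = pl[-nrow(pl), 2],
               x1 = pl[-nrow(pl), 3],
               z2 = pl[-1, 1], y2 = pl[-1, 2], x2 = pl[-1, 3],
               radius = e$radius, label = e$label, seg_length = seg_len)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  b <- tree$metadata$lung_boundary
  meta <- list(
    hilum = tree$metadata$hilum,
    total_baseline_length = tree$metadata$total_baseline_length,
    total_neovessel_length = tree$metadata$total_neovessel_length,
    nodes = tree$nodes
  )
  if (!is.null(b)) {
    meta$lung_boundary <- list(center = b$center, semiaxes = b$semiaxes,
                               hilum = b$hilum)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pulmovasc-io
#' @export
read_vessel_tree <- function(path) {
  seg <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nodes <- as.data.frame(meta$nodes)
  edges <- data.frame(from = integer(), to = integer(), label = character(),
                      length = numeric(), radius = numeric())
  polylines <- list()
  for (i in sort(unique(seg$edge_id))) {
    s <- seg[seg$edge_id == i, ]
    s <- s[order(s$seg), ]
    pl <- unname(as.matrix(rbind(s[1, c("z1", "y1", "x1")],
                                 setNames(s[, c("z2", "y2", "x2")],
                                          c("z1", "y1", "x1")))))
    edges[nrow(edges) + 1L, ] <- list(s$from_id[1], s$to_id[nrow(s)],
                                      s$label[1], sum(s$seg_length),
                                      s$radius[1])
    polylines[[length(polylines) + 1L]] <- pl
  }
  metadata <- list(hilum = meta$hilum,
                   total_baseline_length = meta$total_baseline_length,
                   total_neovessel_length = meta$total_neovessel_length)
  if (!is.null(meta$lung_boundary)) {
    metadata$lung_boundary <- lung_boundary(meta$lung_boundary$center,
                                            meta$lung_boundary$semiaxes,
                                            meta$lung_boundary$hilum)
  }
  vessel_tree(nodes, edges, polylines, metadata)
}

#' @rdname pulmovasc-io
#' @param projection a [projection_image()].
#' @export
write_projection <- function(projection, path) {
  stopifnot(inherits(projection, "projection_image"))
  png::writePNG(projection$pixels / 255, path)
  jsonlite::write_json(
    list(axis = projection$axis, mode = projection$mode,
         pixel_size = projection$pixel_size),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pulmovasc-io
#' @export
read_projection <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    projection_image(round(m * 255), side$axis, side$mode, side$pixel_size)
  } else {
    projection_image(round(m * 255))
  }
}
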