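# Connected-component instance extraction.  Contours exported by an
# auto-segmentation model arrive as one binary volume per structure class;
# instance-level matching needs the individual 3D connected regions.

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be 6, 18 or 26")
  )
  unname(g[keep, , drop = FALSE])
}

#' A single connected contour instance
#'
#' One 3D connected region of a binary mask: the unit on which
#' report-to-contour matching, false-positive labeling and ruling-out
#' operate.
#'
#' @param voxel_indices Integer n x 3 matrix of 0-based voxel indices.
#' @param grid The [voxel_grid()] the indices live on.
#' @param label Free-text label (e.g. `"GTVn_1"`).
#' @return An object of class `contour_instance` with fields
#'   `voxel_indices`, `centroid_mm`, `volume_mm3`, `label`, `grid`.
#' @export
contour_instance <- function(voxel_indices, grid, label = "") {
  voxel_indices <- matrix(as.integer(voxel_indices), ncol = 3)
  if (nrow(voxel_indices) == 0L) stop("empty component")
  structure(list(
    voxel_indices = voxel_indices,
    centroid_mm = centroid_mm(voxel_indices, grid),
    volume_mm3 = nrow(voxel_indices) * voxel_volume(grid),
    label = label,
    grid = grid
  ), class = "contour_instance")
}

#' @export
print.contour_instance <- function(x, ...) {
  cat(sprintf(
    "<contour_instance %s: %d voxels, %.1f mm3, centroid (%.1f, %.1f, %.1f) mm [%s]>\n",
    x$label, nrow(x$voxel_indices), x$volume_mm3,
    x$centroid_mm[1], x$centroid_mm[2], x$centroid_mm[3], x$grid$frame_id))
  invisible(x)
}

#' Centroid of a voxel set in patient mm coordinates
#'
#' The affine image of the arithmetic mean of the 0-based voxel indices.
#'
#' @param instance_voxels Integer n x 3 matrix of 0-based voxel indices.
#' @param grid The [voxel_grid()] the indices live on.
#' @return Length-3 numeric mm coordinate.
#' @export
centroid_mm <- function(instance_voxels, grid) {
  instance_voxels <- matrix(as.numeric(instance_voxels), ncol = 3)
  if (nrow(instance_voxels) == 0L) stop("empty component")
  voxel_to_mm(grid, colMeans(instance_voxels))
}

#' Extract 3D connected components of a binary mask
#'
#' Labels the maximal connected regions of the foreground under the chosen
#' voxel connectivity and returns them as [contour_instance()] objects,
#' ordered by descending volume with ties broken by the lexicographically
#' smallest voxel index.  Components smaller than `min_voxels` are dropped
#' (speckle suppression).
#'
#' @param mask A [binary_mask()].
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @param min_voxels Minimum component size kept; default 2.
#' @param label_prefix Prefix for instance labels (suffix `_1`, `_2`, ...).
#' @return List of `contour_instance` (possibly empty).
#' @examples
#' g <- voxel_grid(c(8, 8, 8))
#' v <- array(FALSE, c(8, 8, 8)); v[1:2, 1, 1] <- TRUE; v[5:6, 5, 5] <- TRUE
#' length(connected_components(binary_mask(g, v)))
#' @export
connected_components <- function(mask, connectivity = 26, min_voxels = 2,
                                 label_prefix = "cc") {
  stopifnot(inherits(mask, "binary_mask"))
  idx0 <- mask_indices(mask)
  n <- nrow(idx0)
  if (n == 0L) return(list())
  shape <- mask$grid$shape
  key <- function(m) m[, 1] + shape[1] * (m[, 2] + shape[2] * m[, 3])
  keys <- key(idx0)
  off <- neighbour_offsets(connectivity)
  # half the offsets suffice: each undirected adjacency is built once
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
            (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(idx0, 2, off[r, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < shape[1] &
          nb[, 2] >= 0 & nb[, 2] < shape[2] &
          nb[, 3] >= 0 & nb[, 3] < shape[3]
    hit <- match(key(nb[ok, , drop = FALSE]), keys)
    from <- which(ok)[!is.na(hit)]
    edges[[r]] <- cbind(from, hit[!is.na(hit)])
  }
  el <- do.call(rbind, edges)
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el) && nrow(el)) gr <- igraph::add_edges(gr, t(el))
  memb <- igraph::components(gr)$membership
  comps <- split(seq_len(n), memb)
  comps <- comps[vapply(comps, length, 1L) >= max(0L, as.integer(min_voxels))]
  if (length(comps) == 0L) return(list())
  # deterministic order: descending size, then lexicographic first voxel
  first_vox <- lapply(comps, function(rows) {
    m <- idx0[rows, , drop = FALSE]
    m[order(m[, 1], m[, 2], m[, 3])[1], ]
  })
  sizes <- vapply(comps, length, 1L)
  fv <- do.call(rbind, first_vox)
  ord <- order(-sizes, fv[, 1], fv[, 2], fv[, 3])
  comps <- comps[ord]
  lapply(seq_along(comps), function(i) {
    contour_instance(idx0[comps[[i]], , drop = FALSE], mask$grid,
                     label = sprintf("%s_%d", label_prefix, i))
  })
}

#' Rebuild a binary mask from a set of contour instances
#' @param instances List of [contour_instance()] sharing one grid.
#' @param grid The target [voxel_grid()].
#' @export
instances_to_mask <- function(instances, grid) {
  v <- array(FALSE, dim = grid$shape)
  for (inst in instances) {
    v[inst$voxel_indices + 1L] <- TRUE
  }
  binary_mask(grid, v)
}
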