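#' Voxel grid with a patient-space affine
#'
#' A `voxel_grid` describes a 3D image lattice: its shape and the 4x4 affine
#' mapping 0-based voxel indices (homogeneous) to patient millimetre
#' coordinates.  All mm coordinates in this package use the DICOM LPS
#' convention: +x towards the patient's left, +y posterior, +z superior.
#'
#' @param shape Integer triple `(nx, ny, nz)`.
#' @param affine 4x4 numeric matrix; must be invertible with strictly
#'   positive voxel spacings (column norms of the 3x3 block).  Defaults to a
#'   diagonal affine built from `spacing` and `origin`.
#' @param frame_id Coordinate-frame label, typically `"CT"` or `"PET"`.
#' @param spacing,origin Convenience arguments used to construct a diagonal
#'   `affine` when none is given.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(64, 64, 80), spacing = c(2, 2, 2), frame_id = "CT")
#' voxel_spacing(g)
#' @export
voxel_grid <- function(shape, affine = NULL, frame_id = "CT",
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing, 3, 3)
    affine[1:3, 4] <- origin
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(!is.finite(affine)) || abs(det(affine)) < 1e-12 || any(sp <= 0)) {
    stop("affine must be invertible with strictly positive voxel spacings")
  }
  structure(list(shape = shape, affine = affine, frame_id = frame_id),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s: %d x %d x %d, spacing %.3g x %.3g x %.3g mm>\n",
              x$frame_id, x$shape[1], x$shape[2], x$shape[3],
              voxel_spacing(x)[1], voxel_spacing(x)[2], voxel_spacing(x)[3]))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
voxel_spacing <- function(grid) sqrt(colSums(grid$affine[1:3, 1:3]^2))

#' Voxel volume of a grid in mm^3
#' @param grid A `voxel_grid`.
#' @export
voxel_volume <- function(grid) abs(det(grid$affine[1:3, 1:3]))

#' Map 0-based voxel indices to patient mm coordinates
#'
#' @param grid A `voxel_grid`.
#' @param idx Numeric vector of length 3 or an n x 3 matrix of 0-based
#'   (possibly fractional) voxel indices.
#' @return mm coordinates, same shape as `idx`.
#' @export
voxel_to_mm <- function(grid, idx) {
  one_row <- is.null(dim(idx))
  m <- rbind(t(matrix(as.numeric(idx), ncol = 3)), 1)
  out <- t(grid$affine %*% m)[, 1:3, drop = FALSE]
  if (one_row) drop(out) else out
}

#' Map patient mm coordinates to continuous 0-based voxel indices
#' @inheritParams voxel_to_mm
#' @param p mm coordinates (length-3 vector or n x 3 matrix).
#' @export
mm_to_voxel <- function(grid, p) {
  one_row <- is.null(dim(p))
  m <- rbind(t(matrix(as.numeric(p), ncol = 3)), 1)
  out <- t(solve(grid$affine) %*% m)[, 1:3, drop = FALSE]
  if (one_row) drop(out) else out
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Binary segmentation mask on a voxel grid
#'
#' @param grid A [voxel_grid()].
#' @param voxels 3D logical (or 0/1) array with `dim == grid$shape`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, voxels = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(voxels)) voxels <- array(FALSE, dim = grid$shape)
  if (!identical(as.integer(dim(voxels)), grid$shape)) {
    stop("voxel array shape does not match grid shape")
  }
  storage.mode(voxels) <- "logical"
  structure(list(grid = grid, voxels = voxels), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask on %s grid %s: %d foreground voxels>\n",
              x$grid$frame_id, paste(x$grid$shape, collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

#' Number of foreground voxels in a mask
#' @param mask A `binary_mask`.
#' @export
mask_count <- function(mask) sum(mask$voxels)

#' 0-based foreground voxel indices of a mask
#' @param mask A `binary_mask`.
#' @return Integer n x 3 matrix of 0-based indices.
#' @export
mask_indices <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  unname(idx) - 1L
}
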