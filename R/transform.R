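# Rigid PET<->CT frame mapping.  Planning CT and PET are rigidly registered
# in the treatment-planning system; the exported 4x4 matrix lets contour
# centroids found on the CT grid be expressed in the PET frame whose slice
# numbers the radiology report refers to.

#' Rigid homogeneous transform between coordinate frames
#'
#' @param matrix 4x4 homogeneous matrix; the bottom row must be
#'   `(0, 0, 0, 1)` and the 3x3 block orthonormal within `tol` (a rigid
#'   rotation, no scaling or shear).  Matrices failing the check are
#'   rejected rather than re-orthogonalised, so a corrupt registration
#'   export fails loudly.
#' @param source_frame,target_frame Frame labels, e.g. `"PET"`, `"CT"`.
#' @param tol Orthonormality tolerance (default `1e-6`).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix, source_frame, target_frame, tol = 1e-6) {
  matrix <- unname(as.matrix(matrix))
  if (!all(dim(matrix) == c(4L, 4L)) || any(!is.finite(matrix))) {
    stop("rigid transform must be a finite 4x4 matrix")
  }
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > tol) {
    stop("rigid transform bottom row must be (0, 0, 0, 1)")
  }
  R <- matrix[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > tol) {
    stop("rigid transform rotation block is not orthonormal (non-rigid matrix)")
  }
  structure(list(matrix = matrix, source_frame = source_frame,
                 target_frame = target_frame),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$source_frame, x$target_frame))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Invert a rigid transform
#'
#' Converts an exported registration matrix to its inverse mapping; e.g. a
#' PET-to-CT matrix becomes the CT-to-PET matrix used to carry CT-frame
#' centroids into the report's PET slice space.
#'
#' @param t A [rigid_transform()].
#' @return A `rigid_transform` mapping `target_frame` to `source_frame`;
#'   composing with the original gives the identity within 1e-9.
#' @export
invert_rigid <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(solve(t$matrix), t$target_frame, t$source_frame)
}

#' Apply a rigid transform to a point
#'
#' @param t A [rigid_transform()].
#' @param p mm coordinate: length-3 vector or n x 3 matrix.
#' @return Transformed coordinates with the shape of `p`.
#' @export
map_point <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  one_row <- is.null(dim(p))
  m <- rbind(t(matrix(as.numeric(p), ncol = 3)), 1)
  if (any(!is.finite(m))) stop("point coordinates must be finite")
  out <- t(t$matrix %*% m)[, 1:3, drop = FALSE]
  if (one_row) drop(out) else out
}

#' Build a rigid transform from Euler angles and a translation
#'
#' Rotation applied as Rz Ry Rx about `center_mm`, then translated.
#'
#' @param angles_deg Rotations about x, y, z in degrees.
#' @param translation_mm Length-3 translation in mm.
#' @param center_mm Rotation centre in mm (default origin).
#' @inheritParams rigid_transform
#' @export
rigid_from_params <- function(angles_deg = c(0, 0, 0),
                              translation_mm = c(0, 0, 0),
                              center_mm = c(0, 0, 0),
                              source_frame = "PET", target_frame = "CT") {
  a <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  R <- rz %*% ry %*% rx
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center_mm - R %*% center_mm + translation_mm
  rigid_transform(m, source_frame, target_frame)
}

#' Read / write a rigid transform as a plain-text matrix file
#'
#' The file holds 4 rows of 4 whitespace-separated floats; an optional
#' header line `# frames: <source> <target>` names the frames.  Some
#' planning systems export the matrix in the opposite (passive) convention;
#' `invert_on_load` flips it at read time rather than guessing.
#'
#' @param path File path.
#' @param source_frame,target_frame Frame labels; overridden by a header
#'   line when present.
#' @param invert_on_load If `TRUE`, the matrix is inverted (and the frames
#'   swapped) as it is read.
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path, source_frame = "PET", target_frame = "CT",
                           invert_on_load = FALSE) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#\\s*frames:", lines, value = TRUE)
  if (length(hdr)) {
    parts <- strsplit(sub("^#\\s*frames:\\s*", "", hdr[1]), "\\s+")[[1]]
    if (length(parts) >= 2) {
      source_frame <- parts[1]
      target_frame <- parts[2]
    }
  }
  num <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(num) != 4L) stop("transform file must contain 4 matrix rows")
  m <- do.call(rbind, lapply(num, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (!all(dim(m) == c(4L, 4L)) || any(is.na(m))) {
    stop("transform file must contain a 4x4 numeric matrix")
  }
  t <- rigid_transform(m, source_frame, target_frame)
  if (invert_on_load) invert_rigid(t) else t
}

#' @rdname read_transform
#' @param t A [rigid_transform()] to write.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frames: %s %s", t$source_frame, t$target_frame), con)
  apply(t$matrix, 1, function(row) {
    writeLines(paste(formatC(row, format = "g", digits = 17), collapse = " "), con)
  })
  invisible(path)
}
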