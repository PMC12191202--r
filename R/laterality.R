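# Laterality and slice-number conversion.  Reports localise lesions as
# left/right of the midsagittal plane and by PET slice number; both tests
# are applied to contour centroids after frame mapping.

#' Midsagittal (midline) plane
#'
#' @param x0_mm Sagittal offset of the plane in mm (LPS x coordinate).
#' @param tolerance_mm Half-width of the band classified as "midline"
#'   (default 5 mm).
#' @param frame Frame label the plane lives in.
#' @return An object of class `midline_plane`.
#' @export
midline_plane <- function(x0_mm = 0, tolerance_mm = 5, frame = "CT") {
  stopifnot(tolerance_mm >= 0)
  structure(list(frame = frame, x0_mm = x0_mm, tolerance_mm = tolerance_mm),
            class = "midline_plane")
}

#' Default midline from a body contour or grid centre
#'
#' The plane sits at the x coordinate of the body/external mask centroid
#' when one is available, else at the mm x of the grid centre.
#'
#' @param grid A [voxel_grid()].
#' @param body_mask Optional external-contour [binary_mask()].
#' @inheritParams midline_plane
#' @export
default_midline <- function(grid, body_mask = NULL, tolerance_mm = 5) {
  x0 <- if (!is.null(body_mask) && mask_count(body_mask) > 0) {
    centroid_mm(mask_indices(body_mask), body_mask$grid)[1]
  } else {
    voxel_to_mm(grid, (grid$shape - 1) / 2)[1]
  }
  midline_plane(x0_mm = x0, tolerance_mm = tolerance_mm, frame = grid$frame_id)
}

#' Laterality of a point relative to the midline
#'
#' Under LPS, +x is the patient's left: points more than `tolerance_mm`
#' left of the plane are `"left"`, mirror-wise `"right"`, and points inside
#' the band are `"midline"`.
#'
#' @param p mm coordinate (length-3) in the plane's frame.
#' @param midline A [midline_plane()].
#' @return `"left"`, `"right"` or `"midline"`.
#' @export
laterality_of <- function(p, midline) {
  stopifnot(inherits(midline, "midline_plane"))
  dx <- p[1] - midline$x0_mm
  if (abs(dx) <= midline$tolerance_mm) "midline"
  else if (dx > 0) "left"
  else "right"
}

#' Convert a point to a report slice number
#'
#' Reports number axial slices starting at 1; whether slice 1 is the most
#' superior or most inferior plane is a per-scanner convention
#' (`numbering`), defaulting to superior-to-inferior.  The point is
#' assigned the nearest axial voxel plane, then converted.
#'
#' @param p mm coordinate in the grid's frame.
#' @param grid The [voxel_grid()] whose axial planes define the slices
#'   (for report matching, the PET grid).
#' @param numbering `"superior_inferior"` (slice 1 most superior; default)
#'   or `"inferior_superior"`.
#' @return Integer slice number in 1..nz.
#' @export
point_to_slice <- function(p, grid, numbering = "superior_inferior") {
  idx <- mm_to_voxel(grid, p)
  if (any(idx < -0.5) || any(idx > grid$shape - 0.5)) stop("point off grid")
  k <- min(max(idx[3], 0), grid$shape[3] - 1)
  nz <- grid$shape[3]
  slice_from_k(k, grid, numbering)
}

# continuous 0-based axial index -> (rounded) report slice number
slice_from_k <- function(k, grid, numbering = "superior_inferior") {
  nz <- grid$shape[3]
  k_is_superior <- grid$affine[3, 3] >= 0  # patient-z grows with k (LPS)
  s <- if (numbering == "superior_inferior") {
    if (k_is_superior) nz - k else k + 1
  } else if (numbering == "inferior_superior") {
    if (k_is_superior) k + 1 else nz - k
  } else stop("unknown slice numbering convention: ", numbering)
  as.integer(round(s))
}

#' Axial slice span of a contour instance on a reporting grid
#'
#' Maps the instance's minimum- and maximum-z voxel centres (in its own
#' frame) through `to_report` onto `report_grid` and returns the inclusive
#' slice range, used to confirm that a contour covers a reported slice.
#'
#' @param instance A [contour_instance()] (typically on the CT grid).
#' @param report_grid The PET [voxel_grid()] carrying report slice numbers.
#' @param to_report [rigid_transform()] from the instance's frame to the
#'   report frame; `NULL` for identity (same frame).
#' @inheritParams point_to_slice
#' @return Integer vector `c(lo, hi)` of slice numbers.
#' @export
instance_slice_span <- function(instance, report_grid, to_report = NULL,
                                numbering = "superior_inferior") {
  mm <- voxel_to_mm(instance$grid, instance$voxel_indices)
  lo_pt <- mm[which.min(mm[, 3]), ]
  hi_pt <- mm[which.max(mm[, 3]), ]
  if (!is.null(to_report)) {
    lo_pt <- map_point(to_report, lo_pt)
    hi_pt <- map_point(to_report, hi_pt)
  }
  s <- c(point_to_slice(lo_pt, report_grid, numbering),
         point_to_slice(hi_pt, report_grid, numbering))
  c(min(s), max(s))
}
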