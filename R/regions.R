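# Anatomic-region bounding boxes.  When a report gives no slice number it
# localises a lesion by lymph-node level or by a named region ("right
# nasopharyngeal region").  Regions are approximated by axis-aligned
# mm-space boxes whose six faces sit on the extents of neighbouring
# organs-at-risk: superior/inferior/left/right/anterior/posterior faces each
# borrow one face of one named OAR.

oar_synonyms <- c(
  "brain_stem" = "brainstem",
  "spinalcord" = "spinal_cord",
  "cord" = "spinal_cord",
  "external" = "body"
)

canonical_structure_name <- function(name) {
  n <- tolower(gsub("[ -]+", "_", trimws(name)))
  if (n %in% names(oar_synonyms)) unname(oar_synonyms[n]) else n
}

#' Organ-at-risk structure set
#'
#' Named binary masks on one shared CT-frame grid: the OARs whose extents
#' define region boxes, plus optional LN-level masks named
#' `level_<label>` (e.g. `level_2a`).
#'
#' @param structures Named list of [binary_mask()] on one grid.
#' @return An object of class `oar_set`.
#' @export
oar_set <- function(structures) {
  stopifnot(length(structures) > 0)
  names(structures) <- vapply(names(structures), canonical_structure_name, "")
  g <- structures[[1]]$grid
  for (s in structures) {
    if (!same_grid(s$grid, g)) stop("all OAR masks must share one voxel grid")
  }
  structure(list(structures = structures, grid = g), class = "oar_set")
}

#' @export
print.oar_set <- function(x, ...) {
  cat(sprintf("<oar_set: %d structures on %s grid (%s)>\n",
              length(x$structures), x$grid$frame_id,
              paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

#' mm-space extent of a structure
#'
#' Minimum and maximum mm coordinates over the voxel centres of the mask's
#' foreground (brute-force over the voxel set).
#'
#' @param mask A [binary_mask()].
#' @return List with `lo_mm`, `hi_mm` (length-3 each).
#' @export
structure_extent <- function(mask) {
  idx <- mask_indices(mask)
  if (nrow(idx) == 0) stop("cannot take the extent of an empty structure")
  mm <- voxel_to_mm(mask$grid, idx)
  list(lo_mm = apply(mm, 2, min), hi_mm = apply(mm, 2, max))
}

# face letter -> (axis, which end) under LPS: L = +x, P = +y, S = +z
face_axis <- c(R = 1, L = 1, A = 2, P = 2, I = 3, S = 3)
face_is_hi <- c(R = FALSE, L = TRUE, A = FALSE, P = TRUE, I = FALSE, S = TRUE)

#' Region definition: which OAR face bounds each box face
#'
#' @param region Region name from [hn_regions].
#' @param bounds Named list with entries `S`, `I`, `L`, `R`, `A`, `P`; each
#'   a `list(structure = <name>, face = <"S"|"I"|"L"|"R"|"A"|"P">)` naming
#'   the OAR and which face of its extent to place that box face on.
#' @return An object of class `region_definition`.
#' @export
region_definition <- function(region, bounds) {
  need <- c("S", "I", "L", "R", "A", "P")
  if (!all(need %in% names(bounds))) {
    stop("region definition must bound all six faces S, I, L, R, A, P")
  }
  structure(list(region = region, bounds = bounds[need]),
            class = "region_definition")
}

#' Load a region-definition table from JSON
#'
#' The packaged default table (`inst/extdata/region_defs.json`) covers the
#' five regions distinguished for primary tumors; it is a deliberately
#' editable placeholder -- sites should adapt the OAR faces to their own
#' structure vocabulary.
#'
#' @param path JSON file; default the packaged table.
#' @return Named list of [region_definition()].
#' @export
read_region_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "region_defs.json", package = "lesionmatch")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  defs <- lapply(names(raw), function(region) {
    bounds <- lapply(raw[[region]], function(b) {
      list(structure = canonical_structure_name(b$structure), face = b$face)
    })
    region_definition(region, bounds)
  })
  names(defs) <- names(raw)
  defs
}

#' Build the mm-space bounding box of an anatomic region
#'
#' Each face of the box is placed on the corresponding extent face of the
#' OAR named in the definition.  For `laterality` `"left"` or `"right"` the
#' contralateral face is replaced by the midline plane, halving the box;
#' `"bilateral"` keeps both lateral faces.  `margin_mm` expands the final
#' box symmetrically to soften boundary effects for lesions near a face.
#'
#' @param defn A [region_definition()].
#' @param oars An [oar_set()] containing every structure the definition
#'   names.
#' @param laterality `"left"`, `"right"` or `"bilateral"` (default).
#' @param midline A [midline_plane()]; required for one-sided boxes.
#' @param margin_mm Non-negative symmetric expansion (default 0).
#' @return An object of class `region_box` with `region`, `lo_mm`, `hi_mm`,
#'   `frame_id`.
#' @export
build_region_box <- function(defn, oars, laterality = "bilateral",
                             midline = NULL, margin_mm = 0) {
  stopifnot(inherits(defn, "region_definition"), inherits(oars, "oar_set"))
  lo <- hi <- numeric(3)
  extents <- list()
  for (face in names(defn$bounds)) {
    b <- defn$bounds[[face]]
    sname <- canonical_structure_name(b$structure)
    if (is.null(oars$structures[[sname]])) {
      stop(sprintf("region '%s' references structure '%s' absent from the OAR set",
                   defn$region, sname))
    }
    if (is.null(extents[[sname]])) {
      extents[[sname]] <- structure_extent(oars$structures[[sname]])
    }
    ext <- extents[[sname]]
    which_face <- b$face
    val <- if (face_is_hi[[which_face]]) ext$hi_mm[face_axis[[which_face]]]
           else ext$lo_mm[face_axis[[which_face]]]
    if (face_is_hi[[face]]) hi[face_axis[[face]]] <- val
    else lo[face_axis[[face]]] <- val
  }
  if (laterality %in% c("left", "right")) {
    if (is.null(midline)) stop("a midline plane is required for one-sided boxes")
    if (laterality == "left") lo[1] <- midline$x0_mm else hi[1] <- midline$x0_mm
  } else if (!laterality %in% c("bilateral", "midline", "unknown")) {
    stop("unknown laterality: ", laterality)
  }
  lo <- lo - margin_mm
  hi <- hi + margin_mm
  if (any(lo >= hi)) stop(sprintf("degenerate region box for '%s'", defn$region))
  structure(list(region = defn$region, lo_mm = lo, hi_mm = hi,
                 frame_id = oars$grid$frame_id),
            class = "region_box")
}

#' Closed-interval containment test
#'
#' @param p mm coordinate (length-3) in the box's frame.
#' @param box A `region_box`.
#' @param frame_id Optional frame of `p`; mismatch with the box errors.
#' @export
point_in_box <- function(p, box, frame_id = NULL) {
  stopifnot(inherits(box, "region_box"))
  if (!is.null(frame_id) && !identical(frame_id, box$frame_id)) {
    stop(sprintf("frame mismatch: point in %s, box in %s", frame_id,
                 box$frame_id))
  }
  all(p >= box$lo_mm) && all(p <= box$hi_mm)
}

#' Lymph-node level containing a point
#'
#' Returns the label of the LN-level mask (`level_*` structures of the OAR
#' set) whose foreground contains the nearest voxel to `p`; `NA` if the
#' point lies in no level.  Where level masks overlap, the smallest-volume
#' level wins (the more specific compartment).
#'
#' @param p mm coordinate in the OAR grid's frame.
#' @param oars An [oar_set()] with at least one `level_*` mask.
#' @return Level label such as `"2a"`, or `NA_character_`.
#' @export
ln_level_of <- function(p, oars) {
  stopifnot(inherits(oars, "oar_set"))
  lvl_names <- grep("^level_", names(oars$structures), value = TRUE)
  if (!length(lvl_names)) stop("no LN-level masks loaded in the OAR set")
  idx <- round(mm_to_voxel(oars$grid, p))
  if (any(idx < 0) || any(idx >= oars$grid$shape)) return(NA_character_)
  hits <- lvl_names[vapply(lvl_names, function(nm) {
    isTRUE(oars$structures[[nm]]$voxels[idx[1] + 1, idx[2] + 1, idx[3] + 1])
  }, TRUE)]
  if (!length(hits)) return(NA_character_)
  vols <- vapply(hits, function(nm) mask_count(oars$structures[[nm]]), 0L)
  sub("^level_", "", hits[order(vols, hits)][1])
}
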