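# The core algorithm: match auto-segmented contour instances to report
# lesion records, label the leftovers (false-positive contours, false-
# negative report lesions) and erase the false positives from the mask.
#
# Two matching scenarios mirror how radiologists localise lesions:
#   scenario 1 -- the report gives a PET slice number: laterality must
#     agree, the candidate with the nearest centroid slice is taken, and
#     the match is confirmed only if the contour covers the reported slice;
#   scenario 2 -- no slice number: nodes must sit in the reported LN level,
#     primaries inside the anatomic-region bounding box.

#' Matching configuration
#'
#' Bundles the geometry context the matcher needs.
#'
#' @param pet_grid PET [voxel_grid()] carrying report slice numbers.
#' @param ct_to_pet [rigid_transform()] from the contour (CT) frame into
#'   the PET frame (the inverse of the exported PET-to-CT registration);
#'   `NULL` when contours already live on the PET grid.
#' @param midline A [midline_plane()] in the contour frame.
#' @param oars Optional [oar_set()] (required for scenario-2 records).
#' @param region_defs Named list of [region_definition()]; default the
#'   packaged table.
#' @param numbering Slice numbering convention (see [point_to_slice()]).
#' @param slice_tolerance Slices of slack in the coverage test (default 0,
#'   the strict rule; 1 absorbs registration rounding).
#' @param margin_mm Region-box expansion in mm (default 0).
#' @export
match_config <- function(pet_grid = NULL, ct_to_pet = NULL, midline = NULL,
                         oars = NULL, region_defs = NULL,
                         numbering = "superior_inferior",
                         slice_tolerance = 0, margin_mm = 0) {
  structure(list(pet_grid = pet_grid, ct_to_pet = ct_to_pet,
                 midline = midline, oars = oars,
                 region_defs = region_defs %||NULL% NULL,
                 numbering = numbering, slice_tolerance = slice_tolerance,
                 margin_mm = margin_mm),
            class = "match_config")
}

`%||NULL%` <- function(a, b) if (is.null(a)) b else a

# canonical deterministic instance order: descending volume, then
# lexicographic first voxel -- makes matching invariant to input permutation
canonical_instance_order <- function(instances) {
  if (!length(instances)) return(integer())
  fv <- t(vapply(instances, function(i) {
    m <- i$voxel_indices
    as.numeric(m[order(m[, 1], m[, 2], m[, 3])[1], ])
  }, numeric(3)))
  vol <- vapply(instances, function(i) i$volume_mm3, 0)
  order(-vol, fv[, 1], fv[, 2], fv[, 3])
}

record_lat_accepts <- function(record_lat, inst_lat) {
  record_lat %in% c("bilateral", "midline", "unknown") ||
    inst_lat == "midline" || record_lat == inst_lat
}

#' Per-case match result
#'
#' The ledger of a matching run: confirmed (instance, record) pairs, the
#' unmatched contour instances (false positives) and the unmatched report
#' records (false negatives).  Every instance lands in exactly one of
#' `pairs` / `false_positives`; every non-grouped record in at most one
#' pair or in `false_negatives`; grouped ("several nodes") records may
#' appear in several pairs but count as one reported lesion.
#'
#' @param case_id Case identifier.
#' @param pairs List of `list(instance = , record = )`.
#' @param false_positives List of [contour_instance()].
#' @param false_negatives Record table of unmatched records.
#' @param scenario `"slice"`, `"region"` or `"mixed"`.
#' @param n_instances Total instances that entered matching.
#' @export
match_result <- function(case_id, pairs, false_positives, false_negatives,
                         scenario, n_instances = length(pairs) +
                           length(false_positives)) {
  if (length(pairs) + length(false_positives) != n_instances) {
    stop("match ledger does not conserve instances")
  }
  structure(list(case_id = case_id, pairs = pairs,
                 false_positives = false_positives,
                 false_negatives = false_negatives,
                 scenario = scenario, n_instances = n_instances),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result %s [%s]: %d pairs, %d FP, %d FN>\n",
              x$case_id, x$scenario, length(x$pairs),
              length(x$false_positives), nrow(x$false_negatives)))
  invisible(x)
}

instance_lat <- function(inst, midline, config) {
  p <- inst$centroid_mm
  if (!identical(inst$grid$frame_id, midline$frame)) {
    if (is.null(config$ct_to_pet)) stop("registration: no transform to the midline frame")
    p <- map_point(config$ct_to_pet, p)
  }
  laterality_of(p, midline)
}

instance_pet_centroid <- function(inst, config) {
  p <- inst$centroid_mm
  if (!identical(inst$grid$frame_id, config$pet_grid$frame_id)) {
    if (is.null(config$ct_to_pet)) {
      stop("registration: missing CT-to-PET transform for slice matching")
    }
    p <- map_point(config$ct_to_pet, p)
  }
  p
}

#' Scenario 1: slice-location matching
#'
#' For each record (processed in ascending reported slice), candidate
#' instances are the still-unmatched ones whose laterality agrees with the
#' record; the candidate whose centroid slice is nearest the reported slice
#' is selected (ties to the larger volume) and the pair is confirmed only
#' if the instance's axial span covers the reported slice within
#' `slice_tolerance`.  Confirmed instances leave the pool.  Grouped records
#' absorb every laterality-consistent candidate covering their slice.
#'
#' @param instances List of [contour_instance()] of one lesion class.
#' @param records Record table of the same class; rows without a slice
#'   number are excluded with a warning (route them to scenario 2).
#' @param config A [match_config()] with `pet_grid` (and `ct_to_pet` when
#'   the instances are not on the PET grid) and `midline` set.
#' @param case_id Case identifier for the result.
#' @return A [match_result()] with scenario `"slice"`.
#' @export
match_scenario1 <- function(instances, records, config, case_id = "") {
  stopifnot(inherits(config, "match_config"), !is.null(config$pet_grid))
  if (is.null(config$midline)) stop("a midline plane is required")
  no_slice <- is.na(records$slice_number)
  if (any(no_slice)) {
    warning(sprintf("%d record(s) without slice number excluded from scenario 1",
                    sum(no_slice)))
    records <- records[!no_slice, , drop = FALSE]
  }
  instances <- instances[canonical_instance_order(instances)]
  n <- length(instances)
  cent_slice <- vapply(instances, function(i) {
    point_to_slice(instance_pet_centroid(i, config), config$pet_grid,
                   config$numbering)
  }, 0L)
  spans <- lapply(instances, function(i) {
    to_rep <- if (identical(i$grid$frame_id, config$pet_grid$frame_id)) NULL
              else config$ct_to_pet
    instance_slice_span(i, config$pet_grid, to_rep, config$numbering)
  })
  lats <- vapply(instances, instance_lat, "", midline = config$midline,
                 config = config)
  covers <- function(j, s) {
    spans[[j]][1] - config$slice_tolerance <= s &&
      s <= spans[[j]][2] + config$slice_tolerance
  }
  available <- rep(TRUE, n)
  pairs <- list()
  fn_rows <- integer()
  for (ri in order(records$slice_number)) {
    rec <- records[ri, , drop = FALSE]
    cand <- which(available & vapply(seq_len(n), function(j) {
      record_lat_accepts(rec$laterality, lats[j])
    }, TRUE))
    if (rec$grouped) {
      hit <- cand[vapply(cand, covers, TRUE, s = rec$slice_number)]
      if (!length(hit)) { fn_rows <- c(fn_rows, ri); next }
      for (j in hit) {
        pairs[[length(pairs) + 1]] <- list(instance = instances[[j]], record = rec)
        available[j] <- FALSE
      }
    } else {
      if (!length(cand)) { fn_rows <- c(fn_rows, ri); next }
      best <- cand[which.min(abs(cent_slice[cand] - rec$slice_number))]
      if (covers(best, rec$slice_number)) {
        pairs[[length(pairs) + 1]] <- list(instance = instances[[best]],
                                           record = rec)
        available[best] <- FALSE
      } else {
        fn_rows <- c(fn_rows, ri)
      }
    }
  }
  match_result(case_id, pairs, instances[available],
               records[sort(fn_rows), , drop = FALSE], "slice",
               n_instances = n)
}

#' Scenario 2: LN-level and anatomic-region matching
#'
#' Node records match instances whose centroid lies in the reported LN
#' level (level mask membership) with agreeing laterality; node records
#' that give only a region are matched by region-box containment, as are
#' primary records.  Grouped records absorb all consistent instances;
#' otherwise the largest consistent instance is taken.
#'
#' @inheritParams match_scenario1
#' @param config A [match_config()]; `oars` is required, `region_defs`
#'   defaults to the packaged table.
#' @return A [match_result()] with scenario `"region"`.
#' @export
match_scenario2 <- function(instances, records, config, case_id = "") {
  stopifnot(inherits(config, "match_config"))
  if (nrow(records) && is.null(config$oars)) {
    stop("an OAR set is required for scenario-2 matching")
  }
  defs <- config$region_defs %||NULL% read_region_definitions()
  instances <- instances[canonical_instance_order(instances)]
  n <- length(instances)
  lats <- if (n) vapply(instances, instance_lat, "", midline = config$midline,
                        config = config) else character()
  levels <- if (n && !is.null(config$oars) &&
                any(grepl("^level_", names(config$oars$structures)))) {
    vapply(instances, function(i) {
      lv <- ln_level_of(i$centroid_mm, config$oars)
      if (is.na(lv)) "" else lv
    }, "")
  } else rep("", n)
  in_region <- function(j, region, laterality) {
    if (is.na(region) || is.null(defs[[region]])) {
      stop("no region definition for '", region, "'")
    }
    box <- build_region_box(defs[[region]], config$oars, laterality,
                            midline = config$midline,
                            margin_mm = config$margin_mm)
    point_in_box(instances[[j]]$centroid_mm, box,
                 frame_id = instances[[j]]$grid$frame_id)
  }
  consistent <- function(j, rec) {
    if (!record_lat_accepts(rec$laterality, lats[j])) return(FALSE)
    if (rec$lesion_class == "node" && !is.na(rec$ln_level)) {
      identical(levels[j], rec$ln_level)
    } else {
      in_region(j, if (rec$lesion_class == "node") rec$anatomic_region
                   else rec$anatomic_region, rec$laterality)
    }
  }
  available <- rep(TRUE, n)
  pairs <- list()
  fn_rows <- integer()
  for (ri in seq_len(nrow(records))) {
    rec <- records[ri, , drop = FALSE]
    if (rec$lesion_class == "node" && is.na(rec$ln_level) &&
        is.na(rec$anatomic_region)) {
      stop("node record with neither LN level nor anatomic region")
    }
    cand <- which(available)
    cand <- cand[vapply(cand, consistent, TRUE, rec = rec)]
    if (!length(cand)) { fn_rows <- c(fn_rows, ri); next }
    hit <- if (rec$grouped) cand else cand[1]  # canonical order: largest first
    for (j in hit) {
      pairs[[length(pairs) + 1]] <- list(instance = instances[[j]], record = rec)
      available[j] <- FALSE
    }
  }
  match_result(case_id, pairs, instances[available],
               records[sort(fn_rows), , drop = FALSE], "region",
               n_instances = n)
}

#' Classify one case: dispatch, match, and merge the ledgers
#'
#' Primary-tumor and nodal instances are matched independently against the
#' records of their class.  Records carrying a slice number go through
#' scenario 1 first; the instances it leaves unmatched then meet the
#' remaining (sliceless) records in scenario 2.  Instances unmatched after
#' both passes are the case's false positives; unmatched records its false
#' negatives.
#'
#' @param instances Named list with elements `primary` and/or `node`, each
#'   a list of [contour_instance()].
#' @param records Record table for the case (both classes).
#' @param config A [match_config()].
#' @param case_id Case identifier.
#' @return A merged [match_result()] (scenario `"slice"`, `"region"` or
#'   `"mixed"`).
#' @export
classify_case <- function(instances, records, config, case_id = "") {
  stopifnot(is.list(instances))
  pairs <- list()
  fps <- list()
  fns <- empty_records()
  used <- character()
  for (cls in c("primary", "node")) {
    insts <- instances[[cls]] %||NULL% list()
    for (k in seq_along(insts)) insts[[k]]$class <- cls
    recs <- records[records$lesion_class == cls, , drop = FALSE]
    s1 <- recs[!is.na(recs$slice_number), , drop = FALSE]
    s2 <- recs[is.na(recs$slice_number), , drop = FALSE]
    pool <- insts
    if (nrow(s1) || (length(pool) && !nrow(s2))) {
      r1 <- match_scenario1(pool, s1, config, case_id = case_id)
      pairs <- c(pairs, r1$pairs)
      fns <- rbind(fns, r1$false_negatives)
      pool <- r1$false_positives
      used <- c(used, "slice")
    }
    if (nrow(s2)) {
      r2 <- match_scenario2(pool, s2, config, case_id = case_id)
      pairs <- c(pairs, r2$pairs)
      fns <- rbind(fns, r2$false_negatives)
      pool <- r2$false_positives
      used <- c(used, "region")
    }
    fps <- c(fps, pool)
  }
  used <- unique(used)
  scenario <- if (length(used) == 1) used else if (!length(used)) "slice" else "mixed"
  match_result(case_id, pairs, fps, fns, scenario,
               n_instances = length(instances$primary %||NULL% list()) +
                 length(instances$node %||NULL% list()))
}

#' Erase false-positive instances from a mask
#'
#' Returns the input mask minus every voxel of the result's false-positive
#' instances (optionally restricted to one lesion class); matched
#' instances are untouched.  Idempotent: applying it to its own output
#' changes nothing.
#'
#' @param mask The [binary_mask()] the instances were extracted from.
#' @param result A [match_result()] built from this mask's instances.
#' @param lesion_class Optionally `"primary"` or `"node"` to erase only the
#'   false positives of that class (instances tagged by [classify_case()]).
#' @return A cleaned [binary_mask()].
#' @export
rule_out <- function(mask, result, lesion_class = NULL) {
  stopifnot(inherits(mask, "binary_mask"), inherits(result, "match_result"))
  v <- mask$voxels
  for (inst in result$false_positives) {
    if (!is.null(lesion_class) && !identical(inst$class, lesion_class)) next
    ids <- inst$voxel_indices + 1L
    present <- v[ids]
    if (all(present)) {
      v[ids] <- FALSE
    } else if (any(present)) {
      # a partially-present component means the ledger was built from a
      # different mask; an all-absent one was already ruled out (idempotence)
      stop("ledger/mask mismatch: false-positive voxels absent from mask")
    }
  }
  binary_mask(mask$grid, v)
}
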