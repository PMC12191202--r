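# NIfTI mask I/O and the end-to-end pipeline.
#
# NIfTI headers describe a RAS+ world; every mm coordinate inside this
# package is LPS (+x patient-left, DICOM convention), so affines are
# converted RAS -> LPS on read (negating the first two rows) and back on
# write.  Binary volumes round-trip losslessly.

ras_to_lps <- diag(c(-1, -1, 1, 1))

#' Read a binary structure mask from NIfTI
#'
#' @param path `.nii` or `.nii.gz` file holding one 3D volume; voxels > 0
#'   are foreground.  The affine is taken from the header (sform/qform)
#'   and converted to LPS.
#' @param frame_id Frame label to stamp on the grid (default `"CT"`).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, frame_id = "CT") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L) stop("mask must be a 3D volume, got ", length(d), "D")
  aff <- ras_to_lps %*% structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  grid <- voxel_grid(d, affine = aff, frame_id = frame_id)
  binary_mask(grid, array(as.vector(img) > 0, dim = d))
}

#' @rdname read_mask
#' @param mask A [binary_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim = mask$grid$shape))
  aff <- ras_to_lps %*% mask$grid$affine  # LPS -> RAS
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a synthetic case to a directory
#'
#' Lays out one case the way the pipeline expects to read it back: NIfTI
#' masks (predictions, ground truth, OARs and LN levels), the PET-to-CT
#' transform as a text matrix, records as JSON, the fixture-dialect and
#' prose report text, and the construction-time truth ledger.
#'
#' @param case A `synthetic_case` from [generate_case()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  for (s in c("GTVp", "GTVn")) {
    write_mask(case$pred[[s]], p(sprintf("pred_%s.nii.gz", s)))
    write_mask(case$gt[[s]], p(sprintf("gt_%s.nii.gz", s)))
  }
  dir.create(p("oars"), showWarnings = FALSE)
  for (nm in names(case$oars$structures)) {
    write_mask(case$oars$structures[[nm]], p("oars", paste0(nm, ".nii.gz")))
  }
  write_transform(case$pet_to_ct, p("pet_to_ct.txt"))
  write_records(case$records, p("records.json"))
  writeLines(case$report_text, p("report_fixture.txt"))
  writeLines(case$prose_text, p("report_prose.txt"))
  jsonlite::write_json(
    list(pet_shape = case$pet_grid$shape,
         pet_affine = case$pet_grid$affine,
         truth = list(
           GTVp = case$truth$GTVp[c("n_instances", "n_fp", "n_fn")],
           GTVn = case$truth$GTVn[c("n_instances", "n_fp", "n_fn")],
           fn_record_rows = case$truth$fn_record_rows)),
    p("case_meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a case directory into pipeline inputs
#'
#' @param dir A directory written by [write_case()] (or laid out the same
#'   way by hand).
#' @return List with `pred`, `gt`, `oars`, `pet_to_ct`, `pet_grid`,
#'   `records`.
#' @export
read_case <- function(dir) {
  p <- function(...) file.path(dir, ...)
  pred <- list(GTVp = read_mask(p("pred_GTVp.nii.gz")),
               GTVn = read_mask(p("pred_GTVn.nii.gz")))
  gt <- if (file.exists(p("gt_GTVp.nii.gz"))) {
    list(GTVp = read_mask(p("gt_GTVp.nii.gz")),
         GTVn = read_mask(p("gt_GTVn.nii.gz")))
  } else NULL
  oar_files <- list.files(p("oars"), pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE)
  oars <- if (length(oar_files)) {
    masks <- lapply(oar_files, read_mask)
    names(masks) <- sub("\\.nii(\\.gz)?$", "", basename(oar_files))
    oar_set(masks)
  } else NULL
  meta <- jsonlite::fromJSON(p("case_meta.json"))
  pet_grid <- voxel_grid(meta$pet_shape, affine = meta$pet_affine,
                         frame_id = "PET")
  list(pred = pred, gt = gt, oars = oars,
       pet_to_ct = read_transform(p("pet_to_ct.txt")),
       pet_grid = pet_grid,
       records = read_records(p("records.json")),
       truth = meta$truth)
}

#' Run the full ruling-out pipeline on one case directory
#'
#' Extracts contour instances from the prediction masks, matches them to
#' the records (scenario dispatch per record), erases the false positives,
#' and -- when ground truth is present -- evaluates DSC/HD95 before and
#' after.  Artifacts written to `out_dir`: `match_result.json` (the
#' FP/FN ledger), `clean_GTVp.nii.gz` / `clean_GTVn.nii.gz`,
#' `metrics.csv`, and `run_log.txt` recording the tolerances and region
#' table used.
#'
#' @param case_dir Input directory (see [read_case()]).
#' @param out_dir Output directory (default `<case_dir>/out`).
#' @param slice_tolerance,margin_mm,numbering Matching tolerances, see
#'   [match_config()].
#' @param min_voxels Speckle threshold for [connected_components()].
#' @return Invisibly, a list with `result` ([match_result()]), `clean`
#'   masks, and `metrics` (data.frame, `NULL` without ground truth).
#' @export
run_pipeline <- function(case_dir, out_dir = file.path(case_dir, "out"),
                         slice_tolerance = 0, margin_mm = 0,
                         numbering = "superior_inferior", min_voxels = 2) {
  inp <- read_case(case_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  body <- if (!is.null(inp$oars)) inp$oars$structures$body else NULL
  ct_grid <- inp$pred$GTVn$grid
  config <- match_config(
    pet_grid = inp$pet_grid,
    ct_to_pet = invert_rigid(inp$pet_to_ct),
    midline = default_midline(ct_grid, body),
    oars = inp$oars,
    numbering = numbering,
    slice_tolerance = slice_tolerance,
    margin_mm = margin_mm)
  instances <- list(
    primary = connected_components(inp$pred$GTVp, min_voxels = min_voxels,
                                   label_prefix = "GTVp"),
    node = connected_components(inp$pred$GTVn, min_voxels = min_voxels,
                                label_prefix = "GTVn"))
  result <- classify_case(instances, inp$records, config,
                          case_id = basename(normalizePath(case_dir)))
  clean <- list(
    GTVp = rule_out(inp$pred$GTVp, result, lesion_class = "primary"),
    GTVn = rule_out(inp$pred$GTVn, result, lesion_class = "node"))
  write_mask(clean$GTVp, file.path(out_dir, "clean_GTVp.nii.gz"))
  write_mask(clean$GTVn, file.path(out_dir, "clean_GTVn.nii.gz"))
  jsonlite::write_json(match_result_summary(result),
                       file.path(out_dir, "match_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  metrics <- NULL
  if (!is.null(inp$gt)) {
    metrics <- do.call(rbind, lapply(c("GTVp", "GTVn"), function(s) {
      rbind(case_metrics(inp$pred[[s]], inp$gt[[s]], result$case_id, s, "before"),
            case_metrics(clean[[s]], inp$gt[[s]], result$case_id, s, "after"))
    }))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, na = "")
  }
  writeLines(c(
    sprintf("case: %s", result$case_id),
    sprintf("scenario: %s", result$scenario),
    sprintf("slice_tolerance: %d  margin_mm: %g  numbering: %s",
            slice_tolerance, margin_mm, numbering),
    sprintf("midline_x0_mm: %.3f  tolerance_mm: %.1f",
            config$midline$x0_mm, config$midline$tolerance_mm),
    sprintf("region_defs: %s", system.file("extdata", "region_defs.json",
                                           package = "lesionmatch")),
    sprintf("pairs: %d  false_positives: %d  false_negatives: %d",
            length(result$pairs), length(result$false_positives),
            nrow(result$false_negatives))
  ), file.path(out_dir, "run_log.txt"))
  invisible(list(result = result, clean = clean, metrics = metrics))
}

#' JSON-ready summary of a match result
#'
#' @param result A [match_result()].
#' @return Plain list: per-pair instance label/centroid and record fields,
#'   false-positive instances, false-negative records, counts.
#' @export
match_result_summary <- function(result) {
  inst_info <- function(i) list(
    label = i$label, class = i$class %||NULL% NA,
    n_voxels = nrow(i$voxel_indices),
    volume_mm3 = i$volume_mm3,
    centroid_mm = as.numeric(i$centroid_mm))
  list(
    case_id = result$case_id,
    scenario = result$scenario,
    n_instances = result$n_instances,
    pairs = lapply(result$pairs, function(p) list(
      instance = inst_info(p$instance),
      record = as.list(p$record[1, c("lesion_class", "laterality",
                                     "slice_number", "anatomic_region",
                                     "ln_level")]))),
    false_positives = lapply(result$false_positives, inst_info),
    false_negatives = result$false_negatives
  )
}
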