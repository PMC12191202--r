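# Synthetic phantom cases.  Each case is a complete desk-scale stand-in for
# one clinical head-and-neck case: a CT grid carrying OAR and LN-level
# masks, ground-truth GTVp/GTVn lesions, "auto-segmentation" prediction
# masks with injected false-positive instances and withheld (false-
# negative) lesions, a rigid PET-CT transform, and the matching report
# records.  Construction guarantees the error structure: every injected FP
# violates at least one matching criterion of its scenario (wrong side,
# slice far beyond coverage, or wrong LN level/region), and every genuine
# prediction satisfies all criteria of exactly one record -- so the
# generator doubles as an analytic oracle for the matching module.
#
# Geometry is deliberately crude: lesions are ellipsoids, OARs and LN
# levels axis-aligned cuboids tiling a neck-like volume.  Matching consumes
# only centroids, extents and containment, so nothing finer is needed.

# ---- phantom layout (mm, LPS, CT frame) ------------------------------------

phantom_oar_boxes <- list(
  body        = list(lo = c(8, 8, 4),    hi = c(118, 118, 156)),
  brainstem   = list(lo = c(55, 60, 120), hi = c(71, 80, 150)),
  spinal_cord = list(lo = c(55, 70, 10),  hi = c(71, 86, 120)),
  mandible    = list(lo = c(30, 20, 90),  hi = c(96, 44, 110)),
  hyoid       = list(lo = c(45, 28, 70),  hi = c(81, 40, 80)),
  cricoid     = list(lo = c(48, 30, 40),  hi = c(78, 46, 56))
)

# nodal level compartments: y/z bands spanning both sides in x
phantom_level_boxes <- list(
  level_1b = list(lo = c(10, 24, 100), hi = c(116, 88, 118)),
  level_2a = list(lo = c(10, 24, 84),  hi = c(116, 56, 100)),
  level_2b = list(lo = c(10, 58, 84),  hi = c(116, 88, 100)),
  level_3  = list(lo = c(10, 24, 66),  hi = c(116, 88, 84)),
  level_4a = list(lo = c(10, 24, 48),  hi = c(116, 88, 66)),
  level_4b = list(lo = c(10, 24, 30),  hi = c(116, 88, 48)),
  level_5a = list(lo = c(10, 90, 66),  hi = c(116, 112, 100)),
  level_5b = list(lo = c(10, 90, 30),  hi = c(116, 112, 66))
)

# half-open cuboid rasterisation (lo <= centre < hi) keeps tiled masks
# disjoint; requires an axis-aligned (diagonal) affine
box_mask <- function(grid, lo, hi) {
  A <- grid$affine
  stopifnot(max(abs(A[1:3, 1:3] - diag(diag(A[1:3, 1:3]), 3))) < 1e-9)
  ax <- lapply(1:3, function(d) A[d, d] * (seq_len(grid$shape[d]) - 1) + A[d, 4])
  inside <- lapply(1:3, function(d) ax[[d]] >= lo[d] & ax[[d]] < hi[d])
  v <- array(FALSE, grid$shape)
  v[inside[[1]], inside[[2]], inside[[3]]] <- TRUE
  binary_mask(grid, v)
}

ellipsoid_mask <- function(grid, center, semi) {
  A <- grid$affine
  ax <- lapply(1:3, function(d) A[d, d] * (seq_len(grid$shape[d]) - 1) + A[d, 4])
  e <- lapply(1:3, function(d) ((ax[[d]] - center[d]) / semi[d])^2)
  v <- outer(outer(e[[1]], e[[2]], "+"), e[[3]], "+") <= 1
  binary_mask(grid, v)
}

mask_union <- function(grid, masks) {
  v <- array(FALSE, grid$shape)
  for (m in masks) v <- v | m$voxels
  binary_mask(grid, v)
}

#' Build the phantom OAR set
#'
#' Six cuboid organs-at-risk (body/external, brainstem, spinal cord,
#' mandible, hyoid, cricoid) plus eight LN-level compartments on the given
#' CT grid; the geometry the packaged region-definition table refers to.
#'
#' @param ct_grid CT [voxel_grid()] (axis-aligned affine).
#' @return An [oar_set()].
#' @export
phantom_oars <- function(ct_grid) {
  boxes <- c(phantom_oar_boxes, phantom_level_boxes)
  oar_set(lapply(boxes, function(b) box_mask(ct_grid, b$lo, b$hi)))
}

# ---- configuration ----------------------------------------------------------

#' Synthetic case configuration
#'
#' Defaults describe a desk-scale head-and-neck case: a 64x64x80 CT grid at
#' 2 mm, a coarser 52x52x64 PET grid at 3 mm, a small rigid PET-to-CT
#' offset, and PET-avidity ranges mirroring clinical experience -- detected
#' lesions with SUVbw in `positive_suv_range`, while withheld
#' (false-negative) nodes draw SUVbw from the PET-negative range
#' 0.97--2.09 that characterises nodes auto-segmentation misses.
#'
#' @param seed Integer; fully determines the case.
#' @param ct_shape,pet_shape Grid shapes (each component >= 32).
#' @param ct_spacing_mm,pet_spacing_mm Positive voxel spacings.
#' @param pet_origin_mm PET-frame origin (mm).
#' @param rigid_params List with `angles_deg` (<= 10 deg) and
#'   `translation_mm` (<= 20 mm) for the PET-to-CT transform, applied about
#'   the CT volume centre.
#' @param n_primary 0 or 1 primary tumors.
#' @param n_nodes Ground-truth (reported) nodal lesions.
#' @param n_fp_nodes,n_fp_primary Injected false-positive instances.
#' @param n_fn_nodes Reported nodes withheld from the prediction
#'   (must be <= `n_nodes`).
#' @param pet_negative_suv_range,positive_suv_range SUVbw draw ranges.
#' @param scenario_mix Fraction of records given a slice number (the rest
#'   are localised by LN level / anatomic region only).
#' @return A `synthetic_case_config`.
#' @export
synthetic_case_config <- function(seed = 1,
                                  ct_shape = c(64, 64, 80),
                                  ct_spacing_mm = c(2, 2, 2),
                                  pet_shape = c(52, 52, 64),
                                  pet_spacing_mm = c(3, 3, 3),
                                  pet_origin_mm = c(-12, -12, -8),
                                  rigid_params = list(
                                    angles_deg = c(0, 0, 6),
                                    translation_mm = c(4, -3, 10)),
                                  n_primary = 1,
                                  n_nodes = 2,
                                  n_fp_nodes = 0,
                                  n_fp_primary = 0,
                                  n_fn_nodes = 0,
                                  pet_negative_suv_range = c(0.97, 2.09),
                                  positive_suv_range = c(2.2, 12.0),
                                  scenario_mix = 0.6) {
  stopifnot(all(ct_shape >= 32), all(pet_shape >= 32),
            all(ct_spacing_mm > 0), all(pet_spacing_mm > 0),
            n_primary %in% 0:1, n_nodes >= 0, n_fp_nodes >= 0,
            n_fp_primary >= 0, n_fn_nodes >= 0, n_fn_nodes <= n_nodes,
            all(abs(rigid_params$angles_deg) <= 10),
            all(abs(rigid_params$translation_mm) <= 20),
            scenario_mix >= 0, scenario_mix <= 1)
  structure(as.list(environment()), class = "synthetic_case_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# ---- slot bookkeeping -------------------------------------------------------
# A "slot" is one (side, level) nodal compartment.  Taking a slot retires
# every same-side slot whose z band overlaps it, so same-side lesions are
# always separated in z by their insets -- the margin that makes the
# slice-matching guarantees analytic.

slot_table <- function() {
  lv <- names(phantom_level_boxes)
  data.frame(side = rep(c("left", "right"), each = length(lv)),
             level = rep(sub("^level_", "", lv), 2),
             stringsAsFactors = FALSE)
}

z_overlaps <- function(a, b) {
  ba <- phantom_level_boxes[[paste0("level_", a)]]
  bb <- phantom_level_boxes[[paste0("level_", b)]]
  min(ba$hi[3], bb$hi[3]) - max(ba$lo[3], bb$lo[3]) > 0
}

take_slot <- function(free) {
  i <- if (nrow(free) == 1) 1L else sample.int(nrow(free), 1)
  slot <- free[i, ]
  keep <- !(free$side == slot$side &
              vapply(free$level, z_overlaps, TRUE, b = slot$level))
  list(slot = slot, free = free[keep, , drop = FALSE])
}

node_position <- function(slot, semi) {
  b <- phantom_level_boxes[[paste0("level_", slot$level)]]
  xr <- if (slot$side == "left") c(80, 100) else c(26, 46)
  c(stats::runif(1, xr[1], xr[2]),
    stats::runif(1, b$lo[2] + semi[2] + 3, b$hi[2] - semi[2] - 3),
    stats::runif(1, b$lo[3] + semi[3] + 3, b$hi[3] - semi[3] - 3))
}

primary_regions_used <- c("nasopharyngeal", "oropharynx", "tongue_base",
                          "hypopharynx")

primary_position <- function(region, side, oars, midline, defs) {
  box <- build_region_box(defs[[region]], oars, side, midline = midline)
  semi <- pmin(stats::runif(3, 6, 10),
               (box$hi_mm - box$lo_mm) / 2 - 4)
  lo <- box$lo_mm + semi + 3
  hi <- box$hi_mm - semi - 3
  # keep well clear of the 5 mm midline band on the chosen side
  if (side == "left") lo[1] <- max(lo[1], midline$x0_mm + midline$tolerance_mm + semi[1] + 3)
  if (side == "right") hi[1] <- min(hi[1], midline$x0_mm - midline$tolerance_mm - semi[1] - 3)
  c2 <- vapply(1:3, function(d) stats::runif(1, lo[d], hi[d]), 0)
  list(center = c2, semi = semi)
}

# ---- the generator ----------------------------------------------------------

#' Generate one synthetic case
#'
#' @param config A [synthetic_case_config()].
#' @return A `synthetic_case`: list with `config`, `ct_grid`, `pet_grid`,
#'   `pet_to_ct` ([rigid_transform()]), `oars`, `midline`, `gt` and `pred`
#'   (each with `GTVp`/`GTVn` masks), `records`, `report_text`
#'   (fixture dialect), `prose_text`, and `truth` -- the construction-time
#'   ledger: per-class instance/FP/FN counts, FP centroids (CT mm) and the
#'   record rows withheld as false negatives.
#' @export
generate_case <- function(config = synthetic_case_config()) {
  stopifnot(inherits(config, "synthetic_case_config"))
  with_seed(config$seed, generate_case_impl(config))
}

generate_case_impl <- function(config) {
  ct_grid <- voxel_grid(config$ct_shape, spacing = config$ct_spacing_mm,
                        frame_id = "CT")
  pet_grid <- voxel_grid(config$pet_shape, spacing = config$pet_spacing_mm,
                         origin = config$pet_origin_mm, frame_id = "PET")
  center <- voxel_to_mm(ct_grid, (ct_grid$shape - 1) / 2)
  pet_to_ct <- rigid_from_params(config$rigid_params$angles_deg,
                                 config$rigid_params$translation_mm,
                                 center_mm = center,
                                 source_frame = "PET", target_frame = "CT")
  ct_to_pet <- invert_rigid(pet_to_ct)
  oars <- phantom_oars(ct_grid)
  midline <- default_midline(ct_grid, oars$structures$body)
  defs <- read_region_definitions()

  free <- slot_table()
  n_slots_needed <- config$n_nodes + config$n_fp_nodes
  lesions <- list()   # each: class, kind (tp/fp/fn), center, semi, side,
                      # level/region, suv, size

  draw_suv <- function(range) stats::runif(1, range[1], range[2])

  # primary tumor (at most one) -----------------------------------------------
  if (config$n_primary == 1) {
    region <- sample(primary_regions_used, 1)
    side <- sample(c("left", "right"), 1)
    pos <- primary_position(region, side, oars, midline, defs)
    lesions[[length(lesions) + 1]] <- list(
      class = "primary", kind = "tp", center = pos$center, semi = pos$semi,
      side = side, region = region, level = NA,
      suv = draw_suv(config$positive_suv_range))
  }
  if (config$n_fp_primary > 0) {
    # opposite side from the genuine primary (either side when none exists):
    # laterality alone rules these out against a one-sided record
    taken_side <- if (config$n_primary == 1) lesions[[1]]$side else NULL
    for (i in seq_len(config$n_fp_primary)) {
      side <- if (!is.null(taken_side)) setdiff(c("left", "right"), taken_side)[1]
              else sample(c("left", "right"), 1)
      region <- sample(primary_regions_used, 1)
      pos <- primary_position(region, side, oars, midline, defs)
      lesions[[length(lesions) + 1]] <- list(
        class = "primary", kind = "fp", center = pos$center, semi = pos$semi,
        side = side, region = region, level = NA,
        suv = draw_suv(config$positive_suv_range))
      taken_side <- side  # several FP primaries stack on the empty side
    }
  }

  # nodes ----------------------------------------------------------------------
  node_kinds <- c(rep("tp", config$n_nodes - config$n_fn_nodes),
                  rep("fn", config$n_fn_nodes),
                  rep("fp", config$n_fp_nodes))
  for (kind in node_kinds) {
    if (!nrow(free)) stop("infeasible geometry: out of nodal slots for this grid")
    got <- take_slot(free)
    free <- got$free
    semi <- c(stats::runif(1, 4, 8), stats::runif(1, 4, 8), stats::runif(1, 3.5, 5))
    lesions[[length(lesions) + 1]] <- list(
      class = "node", kind = kind,
      center = node_position(got$slot, semi), semi = semi,
      side = got$slot$side, region = NA, level = got$slot$level,
      suv = draw_suv(if (kind == "fn") config$pet_negative_suv_range
                     else config$positive_suv_range))
  }

  # masks -----------------------------------------------------------------------
  les_mask <- function(l) ellipsoid_mask(ct_grid, l$center, l$semi)
  pred_shift <- c(0, ct_grid$affine[2, 2], 0)  # +1 voxel posterior
  pred_mask <- function(l) ellipsoid_mask(ct_grid, l$center + pred_shift, l$semi)
  pick <- function(cls, kinds) Filter(function(l) l$class == cls && l$kind %in% kinds, lesions)
  gt <- list(
    GTVp = mask_union(ct_grid, lapply(pick("primary", "tp"), les_mask)),
    GTVn = mask_union(ct_grid, lapply(pick("node", c("tp", "fn")), les_mask))
  )
  pred <- list(
    GTVp = mask_union(ct_grid, c(lapply(pick("primary", "tp"), pred_mask),
                                 lapply(pick("primary", "fp"), les_mask))),
    GTVn = mask_union(ct_grid, c(lapply(pick("node", "tp"), pred_mask),
                                 lapply(pick("node", "fp"), les_mask)))
  )

  # records ---------------------------------------------------------------------
  reported <- Filter(function(l) l$kind %in% c("tp", "fn"), lesions)
  recs <- empty_records()
  fn_rows <- integer()
  for (l in reported) {
    slice <- if (stats::runif(1) < config$scenario_mix) {
      point_to_slice(map_point(ct_to_pet, l$center), pet_grid)
    } else NA
    recs <- rbind(recs, lesion_record(
      case_id = sprintf("case_%04d", config$seed),
      lesion_class = l$class, laterality = l$side, slice_number = slice,
      anatomic_region = if (l$class == "primary") l$region else NA,
      ln_level = if (l$class == "node") l$level else NA,
      size_mm = round(2 * max(l$semi), 1), suv_bw = round(l$suv, 2)))
    if (l$kind == "fn") fn_rows <- c(fn_rows, nrow(recs))
  }

  fp_centroids <- function(cls) {
    fps <- pick(cls, "fp")
    if (!length(fps)) matrix(numeric(), 0, 3)
    else do.call(rbind, lapply(fps, `[[`, "center"))
  }
  truth <- list(
    GTVp = list(n_instances = config$n_primary + 0L,
                n_fp = config$n_fp_primary, n_fn = 0L,
                fp_centroids_mm = fp_centroids("primary")),
    GTVn = list(n_instances = config$n_nodes, n_fp = config$n_fp_nodes,
                n_fn = config$n_fn_nodes,
                fp_centroids_mm = fp_centroids("node")),
    fn_record_rows = fn_rows
  )

  structure(list(
    config = config, ct_grid = ct_grid, pet_grid = pet_grid,
    pet_to_ct = pet_to_ct, oars = oars, midline = midline,
    gt = gt, pred = pred, records = recs,
    report_text = render_report_text(recs),
    prose_text = render_prose_report(recs),
    truth = truth
  ), class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "<synthetic_case seed %d: %d primary + %d nodes GT; pred carries %d FP; %d FN; %d records>\n",
    x$config$seed, x$truth$GTVp$n_instances, x$truth$GTVn$n_instances,
    x$truth$GTVp$n_fp + x$truth$GTVn$n_fp, x$truth$GTVn$n_fn,
    nrow(x$records)))
  invisible(x)
}

#' Prose rendering of lesion records
#'
#' A Findings/Impression style free-text report for the record table, used
#' to exercise the LLM extraction path with the mock backend.
#'
#' @param records A record table.
#' @return A single string with Findings and Impression sections.
#' @export
render_prose_report <- function(records) {
  if (!nrow(records)) {
    return("Findings: No suspicious hypermetabolic lesion identified.\nImpression: No evidence of disease.")
  }
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    where <- if (r$lesion_class == "primary") {
      sprintf("%s %s region", r$laterality, gsub("_", " ", r$anatomic_region))
    } else {
      sprintf("%s level %s", r$laterality, r$ln_level)
    }
    what <- if (r$lesion_class == "primary") "hypermetabolic mass lesion"
            else "hypermetabolic lymph node"
    extras <- c(
      if (!is.na(r$slice_number)) sprintf("slice %d", r$slice_number),
      if (!is.na(r$size_mm)) sprintf("%.1f mm", r$size_mm),
      if (!is.na(r$suv_bw)) sprintf("SUVbw %.2f", r$suv_bw))
    sprintf("There is a %s centered at the %s (%s).", what, where,
            paste(extras, collapse = ", "))
  }, character(1))
  np <- sum(records$lesion_class == "primary")
  nn <- sum(records$lesion_class == "node")
  paste0("Findings: ", paste(lines, collapse = " "), "\n",
         "Impression: ", np, " primary tumor(s) and ", nn,
         " involved lymph node(s) as described above.")
}

#' Markdown lesion table for a record set
#'
#' The table the pinned extraction prompt asks a model to emit; handy for
#' building mock-backend replies and recorded transcripts.
#'
#' @param records A record table.
#' @export
records_to_markdown <- function(records) {
  hdr <- "| lesion_class | laterality | slice_number | region_or_level | size_mm | suv_bw | grouped |"
  sep <- "|---|---|---|---|---|---|---|"
  rows <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    cell <- function(x) if (is.na(x)) "" else as.character(x)
    region <- if (r$lesion_class == "primary") r$anatomic_region else r$ln_level
    paste0("| ", paste(c(r$lesion_class, r$laterality, cell(r$slice_number),
                         cell(region), cell(r$size_mm), cell(r$suv_bw),
                         if (r$grouped) "yes" else "no"), collapse = " | "),
           " |")
  }, character(1))
  paste(c(hdr, sep, rows), collapse = "\n")
}

# ---- cohorts ----------------------------------------------------------------

#' Error-structure allocation for a cohort
#'
#' Distributes lesion and error counts across `n_cases` at the clinical
#' rates the package emulates: about 2.5 nodes and 0.91 primaries per case,
#' false-positive contours concentrated in about a quarter of the cases and
#' one withheld PET-negative node in about a fifth.  At `n_cases = 44` this
#' reproduces the reference error structure exactly: 40 primaries + 111
#' nodes = 151 instances, 22 FPs (5 primary, 17 nodal) and 8 FN nodes.
#'
#' @param n_cases Number of cases.
#' @return Data frame with one row per case: `n_primary`, `n_nodes`,
#'   `n_fp_primary`, `n_fp_nodes`, `n_fn_nodes`.
#' @export
cohort_allocation <- function(n_cases = 44) {
  stopifnot(n_cases >= 1)
  prop <- function(k) round(k / 44 * n_cases)
  n_nodes_total <- prop(111)
  n3 <- max(0, min(n_cases, n_nodes_total - 2 * n_cases))
  n_nodes <- c(rep(3, n3), rep(2, n_cases - n3))
  d <- n_nodes_total - sum(n_nodes)
  if (d != 0 && n_cases >= 1) n_nodes[1] <- n_nodes[1] + d

  fp_n_total <- prop(17)
  fp_n_cases <- min(prop(12), n_cases)
  fp2 <- max(0, fp_n_total - fp_n_cases)
  n_fp_nodes <- integer(n_cases)
  if (fp_n_cases > 0) {
    n_fp_nodes[seq_len(fp_n_cases)] <- c(rep(2, fp2), rep(1, fp_n_cases - fp2))
  }

  fn_total <- min(prop(8), n_cases)
  n_fn_nodes <- integer(n_cases)
  if (fn_total > 0) n_fn_nodes[n_cases - seq_len(fn_total) + 1] <- 1

  no_primary <- min(prop(4), n_cases)
  n_primary <- rep(1L, n_cases)
  if (no_primary > 0) n_primary[n_cases - n_cases %/% 8 - seq_len(no_primary) + 1] <- 0L
  fp_p_total <- prop(5)
  n_fp_primary <- integer(n_cases)
  # false-positive primaries sit first on the cases with no genuine primary
  empty_idx <- which(n_primary == 0)
  take <- utils::head(empty_idx, fp_p_total)
  n_fp_primary[take] <- 1L
  rest <- fp_p_total - length(take)
  if (rest > 0) n_fp_primary[utils::head(which(n_primary == 1), rest)] <- 1L

  data.frame(n_primary = n_primary, n_nodes = n_nodes,
             n_fp_primary = n_fp_primary, n_fp_nodes = n_fp_nodes,
             n_fn_nodes = n_fn_nodes)
}

#' Generate a synthetic cohort
#'
#' Per-case seeds derive from the master seed; per-case error counts come
#' from `allocation` (default [cohort_allocation()]), with all other
#' settings taken from `template`.
#'
#' @param n_cases Number of cases (default 44).
#' @param seed Master seed.
#' @param template A [synthetic_case_config()] supplying everything except
#'   the per-case counts.
#' @param allocation Data frame as returned by [cohort_allocation()].
#' @return List of `synthetic_case`, with attribute `"allocation"`.
#' @export
generate_cohort <- function(n_cases = 44, seed = 1,
                            template = synthetic_case_config(),
                            allocation = cohort_allocation(n_cases)) {
  stopifnot(n_cases >= 1, nrow(allocation) == n_cases)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_cases))
  cases <- lapply(seq_len(n_cases), function(i) {
    cfg <- template
    cfg$seed <- case_seeds[i]
    cfg$n_primary <- allocation$n_primary[i]
    cfg$n_nodes <- allocation$n_nodes[i]
    cfg$n_fp_primary <- allocation$n_fp_primary[i]
    cfg$n_fp_nodes <- allocation$n_fp_nodes[i]
    cfg$n_fn_nodes <- allocation$n_fn_nodes[i]
    cfg <- do.call(synthetic_case_config, cfg[setdiff(names(cfg), character())])
    generate_case(cfg)
  })
  structure(cases, allocation = allocation)
}

#' Aggregate the construction-time truth over a cohort
#'
#' @param cases List of `synthetic_case`.
#' @return List of [error_ledger()]s: `GTVp`, `GTVn`, `overall`.
#' @export
cohort_truth_ledger <- function(cases) {
  g <- function(cls, f) sum(vapply(cases, function(cs) cs$truth[[cls]][[f]], 0))
  list(
    GTVp = error_ledger(g("GTVp", "n_instances"), g("GTVp", "n_fp"), g("GTVp", "n_fn")),
    GTVn = error_ledger(g("GTVn", "n_instances"), g("GTVn", "n_fp"), g("GTVn", "n_fn")),
    overall = error_ledger(
      g("GTVp", "n_instances") + g("GTVn", "n_instances"),
      g("GTVp", "n_fp") + g("GTVn", "n_fp"),
      g("GTVp", "n_fn") + g("GTVn", "n_fn"))
  )
}
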