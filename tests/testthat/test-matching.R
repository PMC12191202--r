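# The matching algorithm: scenario dispatch, FP/FN labeling, ruling-out.

# A hand-built CT/PET setup: identical frames would hide bugs, so the PET
# grid is coarser and offset, with a pure-translation registration.
match_fixture <- function() {
  ct <- tiny_grid(c(40, 40, 60), spacing = c(2, 2, 2), frame_id = "CT")
  pet <- tiny_grid(c(30, 30, 40), spacing = c(4, 4, 4),
                   origin = c(-10, -10, -6), frame_id = "PET")
  pet_to_ct <- rigid_from_params(translation_mm = c(0, 0, 8),
                                 source_frame = "PET", target_frame = "CT")
  list(ct = ct, pet = pet,
       config = match_config(pet_grid = pet,
                             ct_to_pet = invert_rigid(pet_to_ct),
                             midline = midline_plane(x0_mm = 39)))
}

# axis-aligned blob instance spanning [z0, z1] voxel planes at x-centre x
blob <- function(grid, x, y, z0, z1, half = 1) {
  idx <- as.matrix(expand.grid((x - half):(x + half), (y - half):(y + half),
                               z0:z1))
  contour_instance(idx, grid, label = sprintf("blob_x%d_z%d", x, z0))
}

rec_node <- function(lat, slice = NA, level = NA, grouped = FALSE) {
  lesion_record(lesion_class = "node", laterality = lat, slice_number = slice,
                ln_level = level, grouped = grouped)
}

test_that("scenario 1 matches on laterality, nearest slice, and coverage", {
  fx <- match_fixture()
  # left blob (x=30 -> 60 mm > midline 39) spanning CT z planes 20..26
  inst <- blob(fx$ct, 30, 20, 20, 26)
  slice <- point_to_slice(map_point(fx$config$ct_to_pet, inst$centroid_mm),
                          fx$pet)
  res <- match_scenario1(list(inst), rec_node("left", slice), fx$config)
  expect_length(res$pairs, 1)
  expect_length(res$false_positives, 0)
  expect_equal(nrow(res$false_negatives), 0)

  # laterality gate: right-labeled record vs left instance
  res2 <- match_scenario1(list(inst), rec_node("right", slice), fx$config)
  expect_length(res2$pairs, 0)
  expect_length(res2$false_positives, 1)
  expect_equal(nrow(res2$false_negatives), 1)

  # bilateral records accept either side
  res3 <- match_scenario1(list(inst), rec_node("bilateral", slice), fx$config)
  expect_length(res3$pairs, 1)
})

test_that("scenario 1 picks the nearest covering centroid among candidates", {
  fx <- match_fixture()
  # two right-side instances: A spans CT planes 18..24, B spans 28..33
  A <- blob(fx$ct, 8, 20, 18, 24)
  B <- blob(fx$ct, 8, 20, 28, 33)
  slice_near_A <- point_to_slice(map_point(fx$config$ct_to_pet,
                                           voxel_to_mm(fx$ct, c(8, 20, 21))),
                                 fx$pet)
  res <- match_scenario1(list(B, A), rec_node("right", slice_near_A), fx$config)
  expect_length(res$pairs, 1)
  expect_equal(res$pairs[[1]]$instance$label, A$label)
  expect_length(res$false_positives, 1)
  expect_equal(res$false_positives[[1]]$label, B$label)

  # nearest-but-not-covering fails the record (strict coverage rule)
  tiny <- blob(fx$ct, 8, 20, 50, 52)
  res2 <- match_scenario1(list(tiny), rec_node("right", slice_near_A), fx$config)
  expect_length(res2$pairs, 0)
  expect_equal(nrow(res2$false_negatives), 1)
})

test_that("scenario 2 matches nodes by LN level and grouped records absorb", {
  oars <- cuboid_oars()
  g <- oars$grid
  config <- match_config(oars = oars, midline = midline_plane(x0_mm = 30))
  in_2a <- blob(g, 6, 10, 17, 19)     # mm (12,20,36): level 2a, right of 30
  in_3 <- blob(g, 15, 9, 17, 19)      # mm (30,18,36): levels 2a+3 -> 3
  expect_equal(ln_level_of(in_2a$centroid_mm, oars), "2a")
  expect_equal(ln_level_of(in_3$centroid_mm, oars), "3")

  res <- match_scenario2(list(in_2a), rec_node("right", level = "2a"), config)
  expect_length(res$pairs, 1)

  res2 <- match_scenario2(list(in_3), rec_node("right", level = "2a"), config)
  expect_length(res2$pairs, 0)
  expect_length(res2$false_positives, 1)
  expect_equal(nrow(res2$false_negatives), 1)

  # grouped record: several nodes in one level, one reported lesion
  trio <- list(blob(g, 6, 10, 16, 17), blob(g, 8, 10, 18, 19),
               blob(g, 6, 12, 20, 21))
  res3 <- match_scenario2(trio, rec_node("right", level = "2a", grouped = TRUE),
                          config)
  expect_length(res3$pairs, 3)
  expect_length(res3$false_positives, 0)
  expect_equal(nrow(res3$false_negatives), 0)
})

test_that("classify_case dispatches by slice presence and conserves counts", {
  cs <- generate_case(synthetic_case_config(seed = 31, n_nodes = 3,
                                            n_fp_nodes = 1, scenario_mix = 0.5))
  config <- match_config(pet_grid = cs$pet_grid,
                         ct_to_pet = invert_rigid(cs$pet_to_ct),
                         midline = cs$midline, oars = cs$oars)
  instances <- list(
    primary = connected_components(cs$pred$GTVp, label_prefix = "GTVp"),
    node = connected_components(cs$pred$GTVn, label_prefix = "GTVn"))
  res <- classify_case(instances, cs$records, config)
  expect_equal(length(res$pairs) + length(res$false_positives),
               length(instances$primary) + length(instances$node))
  n_non_grouped <- sum(!cs$records$grouped)
  expect_equal(length(res$pairs) + nrow(res$false_negatives), n_non_grouped)

  # no records at all: everything is a false positive
  res_empty <- classify_case(instances, cs$records[0, ], config)
  expect_length(res_empty$pairs, 0)
  expect_equal(length(res_empty$false_positives),
               length(instances$primary) + length(instances$node))
})

test_that("matching is invariant to instance input order", {
  fx <- match_fixture()
  insts <- list(blob(fx$ct, 30, 20, 18, 24), blob(fx$ct, 30, 26, 30, 35),
                blob(fx$ct, 8, 20, 18, 24, half = 2))
  recs <- rbind(
    rec_node("left", point_to_slice(map_point(fx$config$ct_to_pet,
                                              insts[[1]]$centroid_mm), fx$pet)),
    rec_node("left", point_to_slice(map_point(fx$config$ct_to_pet,
                                              insts[[2]]$centroid_mm), fx$pet)))
  fp_key <- function(res) sort(vapply(res$false_positives, function(i) i$label, ""))
  base <- match_scenario1(insts, recs, fx$config)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    res <- match_scenario1(insts[perm], recs, fx$config)
    expect_equal(fp_key(res), fp_key(base))
    expect_equal(length(res$pairs), length(base$pairs))
  }
})

test_that("rule_out erases exactly the false-positive voxels and is idempotent", {
  fx <- match_fixture()
  keep <- blob(fx$ct, 30, 20, 20, 26)
  fp1 <- blob(fx$ct, 8, 20, 40, 44)
  fp2 <- blob(fx$ct, 8, 30, 8, 10)
  mask <- instances_to_mask(list(keep, fp1, fp2), fx$ct)
  slice <- point_to_slice(map_point(fx$config$ct_to_pet, keep$centroid_mm),
                          fx$pet)
  res <- match_scenario1(list(keep, fp1, fp2), rec_node("left", slice),
                         fx$config)
  expect_length(res$false_positives, 2)
  clean <- rule_out(mask, res)
  expect_equal(mask_count(clean),
               mask_count(mask) - nrow(fp1$voxel_indices) - nrow(fp2$voxel_indices))
  expect_true(all(clean$voxels[keep$voxel_indices + 1L]))
  # idempotence
  expect_identical(rule_out(clean, res)$voxels, clean$voxels)
  # no FPs: identity; all FPs: empty
  res_all_fp <- match_scenario1(list(keep, fp1, fp2), rec_node("right", slice),
                                fx$config)
  expect_equal(mask_count(rule_out(mask, res_all_fp)), 0)
  res_none <- match_scenario1(list(keep), rec_node("left", slice), fx$config)
  keep_mask <- instances_to_mask(list(keep), fx$ct)
  expect_identical(rule_out(keep_mask, res_none)$voxels, keep_mask$voxels)
  # ledger/mask mismatch: FP voxels only partially present
  broken <- mask$voxels
  broken[fp1$voxel_indices[1, , drop = FALSE] + 1L] <- FALSE
  expect_error(rule_out(binary_mask(fx$ct, broken), res), "ledger/mask mismatch")
})
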