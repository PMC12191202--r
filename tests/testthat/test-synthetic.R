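# The phantom-case generator: determinism, construction guarantees, and
# its role as the matching oracle.

test_that("generation is deterministic and seed-sensitive", {
  cfg <- synthetic_case_config(seed = 7, n_nodes = 3, n_fp_nodes = 1)
  a <- generate_case(cfg)
  b <- generate_case(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_case(synthetic_case_config(seed = 8, n_nodes = 3, n_fp_nodes = 1))
  expect_false(identical(a$records, c2$records))
  # same counts regardless of seed
  expect_equal(c2$truth$GTVn$n_instances, a$truth$GTVn$n_instances)
})

test_that("injected errors appear in the masks and records by construction", {
  cs <- generate_case(synthetic_case_config(seed = 7, n_nodes = 3,
                                            n_fp_nodes = 1, n_fn_nodes = 1))
  # predictions: (3 - 1 FN) genuine + 1 FP = 3 components
  expect_length(connected_components(cs$pred$GTVn), 3)
  # ground truth holds all reported nodes, including the withheld one
  expect_length(connected_components(cs$gt$GTVn), 3)
  expect_equal(cs$truth$GTVn$n_fp, 1)
  expect_equal(nrow(cs$truth$GTVn$fp_centroids_mm), 1)
  # the FN record exists, has PET-negative SUV, and no prediction near it
  fn <- cs$records[cs$truth$fn_record_rows, ]
  expect_equal(nrow(fn), 1)
  expect_gte(fn$suv_bw, 0.97)
  expect_lte(fn$suv_bw, 2.09)
  detected <- cs$records[-cs$truth$fn_record_rows, ]
  expect_true(all(detected$suv_bw >= 2.2))
})

test_that("false positives never overlap ground truth", {
  for (seed in c(3, 7, 19)) {
    cs <- generate_case(synthetic_case_config(seed = seed, n_nodes = 3,
                                              n_fp_nodes = 2, n_fp_primary = 1))
    for (s in c("GTVp", "GTVn")) {
      res_mask <- cs$pred[[s]]$voxels & cs$gt[[s]]$voxels
      cc_pred <- connected_components(cs$pred[[s]])
      truth_fp <- if (s == "GTVp") cs$truth$GTVp else cs$truth$GTVn
      # each truth FP centroid sits on a predicted component disjoint from GT
      for (i in seq_len(nrow(truth_fp$fp_centroids_mm))) {
        ctr <- truth_fp$fp_centroids_mm[i, ]
        d <- vapply(cc_pred, function(inst) sqrt(sum((inst$centroid_mm - ctr)^2)), 0)
        inst <- cc_pred[[which.min(d)]]
        expect_lt(min(d), 3)
        expect_false(any(cs$gt[[s]]$voxels[inst$voxel_indices + 1L]))
      }
    }
  }
})

test_that("classify_case reproduces the construction-time truth ledger", {
  for (seed in c(2, 7, 23)) {
    cs <- generate_case(synthetic_case_config(
      seed = seed, n_nodes = 4, n_fp_nodes = 2, n_fn_nodes = 1,
      n_fp_primary = 1, scenario_mix = 0.5))
    config <- match_config(pet_grid = cs$pet_grid,
                           ct_to_pet = invert_rigid(cs$pet_to_ct),
                           midline = cs$midline, oars = cs$oars)
    instances <- list(
      primary = connected_components(cs$pred$GTVp, label_prefix = "GTVp"),
      node = connected_components(cs$pred$GTVn, label_prefix = "GTVn"))
    res <- classify_case(instances, cs$records, config)
    expect_equal(length(res$false_positives),
                 cs$truth$GTVp$n_fp + cs$truth$GTVn$n_fp)
    expect_equal(nrow(res$false_negatives), cs$truth$GTVn$n_fn)
    # FN identity: exactly the withheld record rows
    expect_equal(res$false_negatives$suv_bw,
                 cs$records$suv_bw[cs$truth$fn_record_rows])
    # FP identity: classifier FP centroids coincide with injected ones
    truth_ctr <- rbind(cs$truth$GTVp$fp_centroids_mm,
                       cs$truth$GTVn$fp_centroids_mm)
    for (inst in res$false_positives) {
      d <- sqrt(colSums((t(truth_ctr) - inst$centroid_mm)^2))
      expect_lt(min(d), 3)
    }
  }
})

test_that("cohort allocation reproduces the clinical error structure at 44", {
  al <- cohort_allocation(44)
  expect_equal(sum(al$n_primary), 40)
  expect_equal(sum(al$n_nodes), 111)
  expect_equal(sum(al$n_fp_primary), 5)
  expect_equal(sum(al$n_fp_nodes), 17)
  expect_equal(sum(al$n_fn_nodes), 8)
  expect_equal(sum(al$n_primary) + sum(al$n_nodes), 151)
  expect_equal(sum(al$n_fp_nodes > 0), 12)   # GTVn FP-affected cases
  expect_equal(sum(al$n_primary == 0), 4)    # cases with no primary tumor
  expect_true(all(al$n_fn_nodes <= al$n_nodes))
  # nodal FP cases and FN cases are disjoint in the default allocation
  expect_equal(sum(al$n_fp_nodes > 0 & al$n_fn_nodes > 0), 0)
})

test_that("two master seeds give identical counts but different placements", {
  a <- generate_cohort(4, seed = 1)
  b <- generate_cohort(4, seed = 2)
  la <- cohort_truth_ledger(a)
  lb <- cohort_truth_ledger(b)
  expect_identical(unclass(la$overall), unclass(lb$overall))
  expect_false(identical(a[[1]]$records$slice_number,
                         b[[1]]$records$slice_number) &&
               identical(a[[1]]$records$suv_bw, b[[1]]$records$suv_bw))
})

test_that("the generator rejects infeasible geometry", {
  expect_error(generate_case(synthetic_case_config(seed = 1, n_nodes = 9,
                                                   n_fp_nodes = 5)),
               "infeasible|slots")
})
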