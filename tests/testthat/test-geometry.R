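# Voxel-grid geometry: component labeling, centroids, rigid algebra,
# laterality and slice conversion.

test_that("connected components match a flood-fill oracle across connectivities", {
  g <- tiny_grid()
  # diagonal pair: one 26-component, two 6-components
  m <- mask_from_indices(g, rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_length(connected_components(m, 26, min_voxels = 1), 1)
  expect_length(connected_components(m, 6, min_voxels = 1), 2)

  set.seed(42)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:5) {
      m <- random_mask(g, p = 0.25)
      got <- connected_components(m, conn, min_voxels = 0)
      want <- flood_fill_components(m$voxels, conn)
      expect_length(got, length(want))
      key <- function(idx) paste(sort(idx[, 1] + 8 * idx[, 2] + 64 * idx[, 3]),
                                 collapse = ",")
      expect_setequal(vapply(got, function(i) key(i$voxel_indices), ""),
                      vapply(want, key, ""))
    }
  }
})

test_that("components partition the mask and respect min_voxels and ordering", {
  g <- tiny_grid()
  expect_identical(connected_components(binary_mask(g), min_voxels = 0), list())
  single <- mask_from_indices(g, rbind(c(3, 3, 3)))
  cc <- connected_components(single, min_voxels = 1)
  expect_length(cc, 1)
  expect_equal(nrow(cc[[1]]$voxel_indices), 1)
  # speckle suppression: the default drops 1-voxel islands
  expect_length(connected_components(single), 0)

  set.seed(1)
  m <- random_mask(g, p = 0.3)
  cc <- connected_components(m, 26, min_voxels = 0)
  all_idx <- do.call(rbind, lapply(cc, function(i) i$voxel_indices))
  expect_equal(nrow(all_idx), mask_count(m))
  expect_false(anyDuplicated(all_idx) > 0)
  vols <- vapply(cc, function(i) i$volume_mm3, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("centroids are affine means of the voxel indices", {
  g <- tiny_grid()
  expect_equal(centroid_mm(rbind(c(2, 2, 2)), g), c(2, 2, 2))
  expect_equal(centroid_mm(rbind(c(0, 0, 0), c(4, 0, 0)), g), c(2, 0, 0))
  g2 <- tiny_grid(spacing = c(2, 2, 3))
  blk <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(centroid_mm(blk, g2), c(1, 1, 1.5))
  expect_error(centroid_mm(matrix(integer(), 0, 3), g), "empty component")
  # shift equivariance
  set.seed(3)
  idx <- matrix(sample(0:5, 30, replace = TRUE), ncol = 3)
  expect_equal(centroid_mm(idx + 2L, g), centroid_mm(idx, g) + 2)
})

test_that("rigid transforms invert and map points like the matrix oracle", {
  id <- rigid_transform(diag(4), "PET", "CT")
  expect_equal(invert_rigid(id)$matrix, diag(4))
  tr <- rigid_from_params(translation_mm = c(5, 0, 0))
  expect_equal(invert_rigid(tr)$matrix[1:3, 4], c(-5, 0, 0))
  expect_equal(map_point(id, c(1, 2, 3)), c(1, 2, 3))
  expect_equal(map_point(rigid_from_params(translation_mm = c(0, 0, 10)),
                         c(0, 0, 0)), c(0, 0, 10))

  rot <- rigid_from_params(c(0, 0, 90), c(1, 2, 3))
  expect_equal(invert_rigid(rot)$matrix, solve(rot$matrix), tolerance = 1e-9)
  set.seed(5)
  pts <- matrix(runif(15, -40, 40), ncol = 3)
  want <- t(rot$matrix %*% rbind(t(pts), 1))[, 1:3]
  expect_equal(map_point(rot, pts), want, tolerance = 1e-12)
  expect_equal(invert_rigid(rot)$source_frame, "CT")
  expect_equal(invert_rigid(rot)$target_frame, "PET")
})

test_that("non-rigid or degenerate matrices are rejected", {
  bad <- diag(4)
  bad[1, 1] <- 2  # scaling
  expect_error(rigid_transform(bad, "PET", "CT"), "orthonormal")
  bad2 <- diag(4)
  bad2[4, 1] <- 1
  expect_error(rigid_transform(bad2, "PET", "CT"), "bottom row")
})

test_that("invert/map composition is the identity on random rigid transforms", {
  set.seed(7)
  for (i in 1:100) {
    t <- random_rigid()
    p <- runif(3, -80, 80)
    expect_equal(map_point(invert_rigid(t), map_point(t, p)), p,
                 tolerance = 1e-6)
  }
})

test_that("laterality follows LPS and is antisymmetric under reflection", {
  ml <- midline_plane(x0_mm = 0, tolerance_mm = 5)
  expect_equal(laterality_of(c(0, 1, 2), ml), "midline")
  expect_equal(laterality_of(c(40, 0, 0), ml), "left")
  expect_equal(laterality_of(c(-3, 0, 0), ml), "midline")
  expect_equal(laterality_of(c(-40, 0, 0), ml), "right")
  set.seed(9)
  for (i in 1:25) {
    x <- runif(1, -60, 60)
    a <- laterality_of(c(x, 0, 0), ml)
    b <- laterality_of(c(-x, 0, 0), ml)
    expect_equal(a == "midline", b == "midline")
    if (a != "midline") expect_equal(sort(c(a, b)), c("left", "right"))
  }
})

test_that("slice numbering converts planes under both conventions", {
  pet <- tiny_grid(c(16, 16, 64), spacing = c(4, 4, 4), frame_id = "PET")
  top <- voxel_to_mm(pet, c(0, 0, 63))  # most superior plane (+z)
  bot <- voxel_to_mm(pet, c(0, 0, 0))
  expect_equal(point_to_slice(top, pet), 1L)
  expect_equal(point_to_slice(bot, pet), 64L)
  expect_equal(point_to_slice(top, pet, "inferior_superior"), 64L)
  # a point 40% of the way from plane 10 to plane 11 rounds to 10
  k10 <- 64 - 10  # voxel plane carrying slice 10
  p <- voxel_to_mm(pet, c(0, 0, k10 - 0.4))
  expect_equal(point_to_slice(p, pet), 10L)
  expect_error(point_to_slice(c(0, 0, 1e4), pet), "off grid")
})
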