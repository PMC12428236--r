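test_that("Otsu threshold matches the definition on forced cases", {
  # two-level histogram: every split separates the classes equally well,
  # so the lowest tied threshold is returned
  v <- c(rep(0L, 50), rep(10L, 50))
  expect_equal(otsu_threshold(v), 0)
  # small fixed histogram over levels 0..5 against the exhaustive oracle
  counts <- c(4, 2, 0, 0, 3, 5)
  v2 <- rep(0:5, counts)
  expect_equal(otsu_threshold(v2), otsu_brute(counts, 0:5))
  expect_error(otsu_threshold(rep(7L, 10)), "degenerate")
})

test_that("Otsu threshold equals the exhaustive oracle on random histograms", {
  set.seed(101)
  for (i in 1:200) {
    nlev <- sample(3:30, 1)
    counts <- rpois(nlev, lambda = sample(1:20, 1))
    if (sum(counts > 0) < 2) counts[1:2] <- counts[1:2] + 1
    v <- rep(seq_len(nlev) - 1L, counts)
    expect_equal(otsu_threshold(v), otsu_brute(counts, seq_len(nlev) - 1L))
  }
})

test_that("binarize applies threshold, connectivity and the noise filter", {
  # three objects of sizes 3, 50, 700 (well separated blocks)
  m <- array(FALSE, c(12, 12, 30))
  m[1:3, 1, 1] <- TRUE                 # 3 voxels
  m[1:2, 1:5, 10:14] <- TRUE           # 50
  m[1:7, 1:10, 20:29] <- TRUE          # 700
  g <- voxel_grid(array(as.integer(m) * 10L, dim(m)), c(1, 1, 1))
  lm <- binarize(g, threshold = 5, min_object_voxels = 10)
  expect_equal(lm$n_objects, 2L)
  # diagonal pair: one object under 26-connectivity, two under 6
  m2 <- array(FALSE, c(2, 2, 2)); m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(label_mask(m2, connectivity = 26)$n_objects, 1L)
  expect_equal(label_mask(m2, connectivity = 6)$n_objects, 2L)
  expect_equal(label_mask(m2, connectivity = 6, min_object_voxels = 2)$n_objects, 0L)
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:6) {
    m <- array(runif(10 * 10 * 10) < 0.12, c(10, 10, 10))
    for (conn in c(6, 26)) {
      expect_equal(label_mask(m, connectivity = conn)$n_objects,
                   count_components_brute(m, conn))
    }
  }
})

test_that("labeling partitions the post-filter foreground", {
  set.seed(7)
  m <- array(runif(15 * 15 * 15) < 0.2, c(15, 15, 15))
  lm <- label_mask(m, min_object_voxels = 5)
  sizes <- tabulate(lm$labels[lm$labels > 0], nbins = lm$n_objects)
  expect_true(all(sizes >= 5))
  expect_equal(sum(sizes), sum(lm$labels > 0))
})

test_that("noise filter is monotone in min_object_voxels", {
  set.seed(8)
  m <- array(runif(12^3) < 0.15, c(12, 12, 12))
  counts <- vapply(c(1, 2, 5, 10, 20),
                   function(k) label_mask(m, min_object_voxels = k)$n_objects,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("size-gate calibration from reference cells", {
  # disjoint cuboids with voxel counts 5, 120, 450, 2000, 9000
  m <- array(FALSE, c(30, 40, 60))
  m[1, 1, 1:5] <- TRUE                 # 5
  m[5:8, 5:10, 10:14] <- TRUE          # 4*6*5 = 120
  m[12:20, 12:21, 20:24] <- TRUE       # 9*10*5 = 450
  m[1:10, 25:34, 30:49] <- TRUE        # 10*10*20 = 2000
  m[15:29, 21:40, 30:59] <- TRUE       # 15*20*30 = 9000
  lm <- label_mask(m)
  st <- object_size_table(lm)
  # pick the 2000-voxel object as largest single cell, 120 as smallest
  id2000 <- st$cell_id[which(st$voxel_count == 2000)]
  id120 <- st$cell_id[which(st$voxel_count == 120)]
  gate <- calibrate_size_gate(lm, largest_single_cell = id2000,
                              smallest_complete_cell = id120)
  expect_equal(unname(gate), c(120, 2000))
  cells <- select_cells(lm, gate = gate, interior_min = 0)
  kept <- audit_table(cells)
  expect_setequal(kept$voxel_count[kept$included],
                  st$voxel_count[st$voxel_count >= 120 & st$voxel_count <= 2000])
  expect_true(all(kept$exclusion_reason[kept$voxel_count < 120] == "too_small"))
  expect_true(all(kept$exclusion_reason[kept$voxel_count > 2000] == "too_large"))
  # same object as both ends keeps exactly that size
  gate1 <- calibrate_size_gate(lm, id120, id120)
  expect_equal(unname(gate1), c(120, 120))
  # inconsistent picks
  expect_error(calibrate_size_gate(lm, id120, id2000), "inconsistent")
  expect_error(calibrate_size_gate(lm, 999, id120), "not present")
})

test_that("border filter marks incomplete cells and is idempotent", {
  m <- array(FALSE, c(10, 10, 10))
  m[4:6, 4:6, 4:6] <- TRUE             # fully interior
  m[1:5, 1:2, 1:2] <- TRUE             # touches three faces heavily
  cells <- extract_cells(label_mask(m))
  au <- audit_table(filter_incomplete(cells, interior_min = 0.8))
  interior <- au[au$interior_fraction == 1, ]
  border <- au[au$interior_fraction < 1, ]
  expect_true(all(interior$included))
  expect_true(all(!border$included))
  expect_true(all(border$exclusion_reason == "incomplete"))
  # interior_min = 0 excludes nothing
  au0 <- audit_table(filter_incomplete(cells, interior_min = 0))
  expect_true(all(au0$included))
  # idempotent
  twice <- filter_incomplete(filter_incomplete(cells, 0.8), 0.8)
  expect_identical(audit_table(twice), au)
})

test_that("manual overrides win over automatic filters", {
  m <- array(FALSE, c(10, 10, 10))
  m[4:6, 4:6, 4:6] <- TRUE
  m[9, 9, 9] <- TRUE   # 1 voxel, on boundary
  lm <- label_mask(m)
  gate <- c(min_voxels = 5, max_voxels = 100)
  plain <- audit_table(select_cells(lm, gate = gate))
  small_id <- plain$cell_id[plain$voxel_count == 1]
  big_id <- plain$cell_id[plain$voxel_count == 27]
  expect_false(plain$included[plain$cell_id == small_id])
  re_in <- select_cells(lm, gate = gate, manual_overrides =
                          list(list(cell_id = small_id, action = "include")))
  au <- audit_table(re_in)
  expect_true(au$included[au$cell_id == small_id])
  expect_equal(au$exclusion_reason[au$cell_id == small_id], "none")
  ex <- select_cells(lm, gate = gate, manual_overrides =
                       list(list(cell_id = big_id, action = "exclude")))
  expect_false(audit_table(ex)$included[audit_table(ex)$cell_id == big_id])
  expect_error(select_cells(lm, manual_overrides =
                              list(list(cell_id = 99, action = "include"))),
               "unknown cell id")
})
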