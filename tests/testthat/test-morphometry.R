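test_that("cell volume is voxel count times voxel volume", {
  m <- array(FALSE, c(5, 10, 10)); m[1:2, 1:5, 1:10] <- TRUE  # 100 voxels
  cl <- first_cell(m, spacing = c(1.0, 0.5, 0.5))
  expect_equal(cell_volume(cl), 25.0)
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  cl1 <- first_cell(m1, spacing = c(0.5, 0.172, 0.172))
  expect_equal(cell_volume(cl1), 0.5 * 0.172^2, tolerance = 1e-12)
  # linearity: doubling the voxel count doubles the volume
  m2 <- m; m2[3:4, 1:5, 1:10] <- TRUE
  cl2 <- first_cell(m2, spacing = c(1.0, 0.5, 0.5))
  expect_equal(cell_volume(cl2), 2 * cell_volume(cl))
})

test_that("territory of a filled cuboid equals its corner span", {
  m <- array(FALSE, c(15, 15, 15)); m[2:12, 2:12, 2:12] <- TRUE
  cl <- first_cell(m, spacing = c(1, 1, 1))
  terr <- territory_volume(cl)
  expect_false(terr$degenerate_territory)
  # hull of the voxel centers of an 11-cube spans its corners: 10^3
  expect_equal(terr$hull_um3, 1000, tolerance = 1e-9)
  # the reported territory of a filled solid is clamped at its voxel volume
  expect_equal(terr$territory_um3, cell_volume(cl))
})

test_that("hull volume matches the facet-enumeration oracle on random clouds", {
  set.seed(99)
  for (i in 1:12) {
    n <- sample(10:40, 1)
    pts <- matrix(runif(3 * n, 0, 10), n, 3)
    h <- gliamorph:::.hull3_volume(pts)
    expect_false(h$degenerate)
    expect_equal(h$volume, hull_volume_brute(pts), tolerance = 1e-8)
  }
})

test_that("hull volume is monotone under taking subsets", {
  set.seed(5)
  pts <- matrix(runif(90, 0, 10), 30, 3)
  sub <- pts[sample(30, 15), ]
  expect_gte(gliamorph:::.hull3_volume(pts)$volume,
             gliamorph:::.hull3_volume(sub)$volume - 1e-9)
})

test_that("degenerate (coplanar) cells get territory = volume and RI = 1", {
  m <- array(FALSE, c(5, 8, 8)); m[3, 2:6, 2:6] <- TRUE  # one-voxel-thick sheet
  cl <- first_cell(m, spacing = c(1, 1, 1))
  terr <- territory_volume(cl)
  expect_true(terr$degenerate_territory)
  expect_equal(ramification_index(terr$territory_um3, cell_volume(cl)), 1)
  expect_error(ramification_index(10, 0), "positive")
})

test_that("ramification index of a solid ball is near 1", {
  cl <- first_cell(make_ball_mask(r_vox = 8))
  ri <- ramification_index(territory_volume(cl)$territory_um3, cell_volume(cl))
  expect_gte(ri, 1 - 1e-9)
  expect_lte(ri, 1.10)  # discretization tolerance at radius >= 8 voxels
})

test_that("simple geometric phantoms skeletonize to their known topology", {
  # straight rod: a single branch with two endpoints
  rod <- first_cell(make_rod_mask(len_vox = 41, r_vox = 2))
  bm <- branch_metrics(skeletonize(rod))
  expect_equal(bm$branchpoints, 0L)
  expect_equal(bm$endpoints, 2L)
  expect_equal(bm$min_branch_um, bm$max_branch_um)
  expect_equal(bm$avg_branch_um, 40, tolerance = 2 / 40)  # +-2 voxel pitches
  # ball: degenerate, all metrics zero
  ball <- first_cell(make_ball_mask(r_vox = 8))
  skb <- skeletonize(ball)
  expect_true(skb$degenerate)
  bmb <- branch_metrics(skb)
  expect_equal(bmb$branchpoints, 0L)
  expect_equal(bmb$endpoints, 0L)
  expect_equal(bmb$avg_branch_um, 0)
  # Y: one bifurcation, three endpoints
  y <- first_cell(make_y_mask())
  bmy <- branch_metrics(skeletonize(y))
  expect_equal(bmy$branchpoints, 1L)
  expect_equal(bmy$endpoints, 3L)
})

test_that("soma detection finds the thickest point", {
  ball <- first_cell(make_ball_mask(r_vox = 8, pad = 3))
  so <- soma(ball)
  ctr_true <- rep(11, 3)  # voxel (12,12,12) -> physical 11 at unit spacing
  expect_lte(max(abs(so$centroid - ctr_true)), 1)
  expect_lte(so$soma_um3, cell_volume(ball))
  rod <- first_cell(make_rod_mask())
  expect_lt(soma(rod)$soma_um3, cell_volume(rod))
  # limiting case: soma_fraction 1 keeps only the distance-transform argmax set
  so1 <- soma(ball, soma_fraction = 1)
  expect_lte(so1$soma_um3, so$soma_um3)
})

test_that("Sholl profile of a rod matches the closed form", {
  rod <- first_cell(make_rod_mask(len_vox = 61, r_vox = 2))
  sk <- skeletonize(rod)
  so <- soma(rod)
  # rod of 60 um from its center: spheres at 5..30 about the rod center
  # each cross the axis exactly once on each side
  ctr <- colMeans(sweep(sk$coords - 1, 2, sk$spacing, "*"))
  pr <- sholl(sk, ctr, step = 5, max_radius = 28)
  expect_equal(pr$intersections, rep(2L, nrow(pr)))
  # degenerate skeleton: all zeros
  ball <- first_cell(make_ball_mask())
  pr0 <- sholl(skeletonize(ball), c(0, 0, 0), step = 5, max_radius = 20)
  expect_true(all(pr0$intersections == 0))
})

test_that("measure_cells assembles records for included cells only", {
  set.seed(3)
  ph <- generate_phantom_stack(list(phantom_spec("amoeboid", seed = 5),
                                    phantom_spec("intermediate", seed = 6)),
                               placement_seed = 4)
  lm <- label_mask(ph$grid$data > 10, spacing = ph$grid$spacing)
  cells <- select_cells(lm, interior_min = 0)
  cells[[2]]$included <- FALSE
  cells[[2]]$exclusion_reason <- "manual"
  out <- measure_cells(cells, default_config())
  expect_equal(nrow(out$records), 1L)
  r <- out$records
  expect_true(all(r$territory_um3 >= r$cell_volume_um3))
  expect_true(all(r$ramification_index >= 1))
  expect_true(all(r$min_branch_um <= r$avg_branch_um &
                  r$avg_branch_um <= r$max_branch_um))
  # determinism: identical output on rerun
  out2 <- measure_cells(cells, default_config())
  expect_identical(out, out2)
})

test_that("morphometric record invariants hold across random phantoms", {
  for (s in 1:8) {
    arch <- c("amoeboid", "intermediate", "ramified")[(s %% 3) + 1]
    ph <- generate_phantom_stack(phantom_spec(arch, seed = 400 + s),
                                 placement_seed = 400 + s)
    seg <- segment_stack(ph$grid)
    out <- measure_cells(seg$cells, default_config())
    r <- out$records
    expect_true(all(r$territory_um3 >= r$cell_volume_um3 - 1e-9))
    expect_true(all(r$ramification_index >= 1 - 1e-9))
    ok <- !r$degenerate_skeleton
    expect_true(all(r$min_branch_um[ok] <= r$avg_branch_um[ok] + 1e-9))
    expect_true(all(r$avg_branch_um[ok] <= r$max_branch_um[ok] + 1e-9))
    expect_true(all(r$branchpoints[!ok] == 0 & r$endpoints[!ok] == 0))
    expect_true(all(r$soma_um3 <= r$cell_volume_um3 + 1e-9))
  }
})

test_that("volumes and lengths scale correctly with voxel spacing", {
  y <- make_y_mask()
  cl1 <- first_cell(y, spacing = c(1, 1, 1))
  cl2 <- first_cell(y, spacing = c(2, 2, 2))
  expect_equal(cell_volume(cl2), 8 * cell_volume(cl1))
  t1 <- territory_volume(cl1)$territory_um3
  t2 <- territory_volume(cl2)$territory_um3
  expect_equal(t2, 8 * t1, tolerance = 1e-9)
  b1 <- branch_metrics(skeletonize(cl1, prune_length = 2))
  b2 <- branch_metrics(skeletonize(cl2, prune_length = 4))
  expect_equal(b2$avg_branch_um, 2 * b1$avg_branch_um, tolerance = 1e-9)
  expect_equal(b1$endpoints, b2$endpoints)
})
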