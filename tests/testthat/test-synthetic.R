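test_that("phantom specs validate their geometry", {
  expect_error(phantom_spec("amoeboid", max_branch_depth = 3), "amoeboid")
  expect_error(phantom_spec("ramified", max_branch_depth = 1), "ramified")
  expect_error(phantom_spec(soma_radius = 0.5, branch_radius = 0.8),
               "soma_radius")
  expect_error(phantom_spec(bifurcation_prob = 1.5), "bifurcation_prob")
})

test_that("a single unbranched process yields the forced topology", {
  sp <- phantom_spec("amoeboid", n_primary_branches = 1, max_branch_depth = 1,
                     bifurcation_prob = 0, seed = 2)
  ph <- generate_phantom_stack(sp, placement_seed = 2)
  tr <- ph$truth[[1]]
  expect_equal(tr$branchpoints, 0L)
  expect_equal(tr$endpoints, 2L)
  expect_equal(length(tr$branch_lengths_um), 1L)
})

test_that("phantom generation is deterministic for fixed seeds", {
  sp <- phantom_spec("intermediate", seed = 12, noise_sd = 15)
  a <- generate_phantom_stack(sp, placement_seed = 12)
  b <- generate_phantom_stack(sp, placement_seed = 12)
  expect_identical(a$grid$data, b$grid$data)
  expect_identical(a$truth, b$truth)
})

test_that("generated trees satisfy the tree identity", {
  for (s in 1:20) {
    sp <- phantom_spec("ramified", seed = 900 + s)
    set.seed(sp$seed)
    tree <- gliamorph:::grow_tree(sp)
    nn <- nrow(tree$nodes)
    deg <- tabulate(c(tree$seg_from, tree$seg_to), nbins = nn)
    tr <- gliamorph:::tree_truth(tree, sp)
    jdeg <- deg[deg >= 3]
    expect_equal(tr$endpoints, 2L + sum(jdeg - 2L))
    expect_equal(tr$branchpoints, length(jdeg))
    # every branch exceeds the resolvability floor
    expect_true(all(tr$branch_lengths_um > 5))
  }
})

test_that("rendered phantom volume approximates the analytic value", {
  for (s in 1:5) {
    sp <- phantom_spec("intermediate", seed = 700 + s)
    ph <- generate_phantom_stack(sp, placement_seed = 700 + s)
    vol_vox <- sum(ph$labels == 1) * prod(ph$grid$spacing)
    expect_equal(vol_vox, ph$truth[[1]]$cell_volume_um3_analytic,
                 tolerance = 0.15)
  }
})

test_that("multi-cell placement respects non-overlap or fails loudly", {
  specs <- lapply(1:3, function(k) phantom_spec("amoeboid", seed = k))
  ph <- generate_phantom_stack(specs, grid_shape = c(120, 160, 160),
                               placement_seed = 7)
  expect_equal(sort(unique(as.vector(ph$labels))), 0:3)
  # labels partition: components of each label are one cell
  for (i in 1:3)
    expect_equal(label_mask(ph$labels == i)$n_objects, 1L)
  expect_error(generate_phantom_stack(specs, grid_shape = c(30, 30, 30),
                                      placement_seed = 1), "grid too small|place")
})

test_that("feature tables have exact composition and hidden labels", {
  tab <- generate_feature_table(c(10, 10, 10), seed = 5)
  expect_equal(nrow(tab), 30)
  expect_equal(unname(table(tab$archetype)[c("amoeboid", "intermediate",
                                             "ramified")]),
               c(10L, 10L, 10L), ignore_attr = TRUE)
  expect_true(all(morph_features() %in% names(tab)))
  expect_error(generate_feature_table(c(5, 5, 5),
                                      sds = matrix(0, 3, 8,
                                                   dimnames = list(
                                                     rownames(feature_archetype_params()$means),
                                                     morph_features()))),
               "positive")
})

test_that("group mixtures shift composition, not parameter values", {
  set.seed(1)
  tab <- generate_group_mixture(2000, prop_veh = c(1, 1, 1) / 3,
                                prop_atp = c(0.5, 0.3, 0.2), seed = 8)
  pv <- prop.table(table(tab$archetype[tab$group == "VEH"]))
  pa <- prop.table(table(tab$archetype[tab$group == "ATP"]))
  expect_equal(unname(pv[c("amoeboid", "intermediate", "ramified")]),
               c(1, 1, 1) / 3, tolerance = 0.08, ignore_attr = TRUE)
  expect_equal(unname(pa[c("amoeboid", "intermediate", "ramified")]),
               c(0.5, 0.3, 0.2), tolerance = 0.08, ignore_attr = TRUE)
  # within an archetype the feature distribution is the same in both groups
  am <- tab[tab$archetype == "ramified", ]
  expect_equal(mean(am$territory_um3[am$group == "VEH"]),
               mean(am$territory_um3[am$group == "ATP"]), tolerance = 0.05)
})

test_that("measured morphometry recovers generator ground truth", {
  # a focused version of the recovery property: one phantom per archetype
  for (arch in c("amoeboid", "intermediate", "ramified")) {
    sp <- phantom_spec(arch, seed = 123)
    ph <- generate_phantom_stack(sp, placement_seed = 123)
    seg <- segment_stack(ph$grid)
    cl <- Filter(function(c) c$included, seg$cells)
    expect_length(cl, 1)
    bm <- branch_metrics(skeletonize(cl[[1]]))
    tr <- ph$truth[[1]]
    expect_equal(bm$branchpoints, tr$branchpoints)
    expect_equal(bm$endpoints, tr$endpoints)
  }
})
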