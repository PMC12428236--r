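fake_records <- function(x, extra_meta = TRUE) {
  df <- as.data.frame(x)
  names(df) <- morph_features()[seq_len(ncol(x))]
  if (extra_meta) {
    df$cell_id <- seq_len(nrow(df))
    df$group <- rep(c("VEH", "ATP"), length.out = nrow(df))
  }
  df
}

test_that("zscore uses the pooled sample SD and flags constant columns", {
  x <- cbind(c(2, 4, 6), c(5, 5, 5), c(1, 2, 9))
  df <- fake_records(x)
  fm <- suppressWarnings(zscore_features(df, features = names(df)[1:3]))
  expect_equal(unname(fm$x[, 1]), c(-1, 0, 1))
  expect_equal(unname(fm$x[, 2]), c(0, 0, 0))
  expect_equal(fm$constant, names(df)[2])
  expect_warning(zscore_features(df, features = names(df)[1:3]), "constant")
  # every non-constant output column has mean 0 and sample SD 1
  expect_equal(unname(colMeans(fm$x[, c(1, 3)])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(fm$x[, c(1, 3)], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(zscore_features(df[1, , drop = FALSE], names(df)[1:3]),
               "at least 2")
})

test_that("rows with missing parameters are dropped with a message", {
  x <- matrix(rnorm(40), 10, 4)
  x[3, 2] <- NA
  df <- fake_records(x)
  expect_message(fm <- zscore_features(df, names(df)[1:4]), "dropped")
  expect_equal(nrow(fm$x), 9)
})

test_that("PCA matches an independent SVD oracle and sums to 100%", {
  set.seed(21)
  x <- matrix(rnorm(100), 20, 5)
  df <- fake_records(x)
  fm <- zscore_features(df, names(df)[1:5])
  pc <- pca_features(fm)
  expect_equal(sum(pc$variance_explained), 100, tolerance = 1e-6)
  expect_true(all(diff(pc$variance_explained) <= 1e-9))
  # oracle: singular value decomposition of the centered standardized matrix
  sv <- svd(scale(fm$x, center = TRUE, scale = FALSE))
  lam <- sv$d^2 / (nrow(x) - 1)
  expect_equal(unname(pc$variance_explained), 100 * lam / sum(lam),
               tolerance = 1e-8)
  expect_equal(abs(unname(pc$loading_matrix)), abs(sv$v), tolerance = 1e-8)
  # sign convention: largest-magnitude loading entry positive
  for (j in 1:5) expect_gt(pc$loading_matrix[which.max(abs(pc$loading_matrix[, j])), j], 0)
  # perfectly correlated pair: PC1 explains everything
  x2 <- cbind(rnorm(15)); x2 <- cbind(x2, 2 * x2)
  fm2 <- zscore_features(fake_records(x2), morph_features()[1:2])
  pc2 <- pca_features(fm2)
  expect_equal(pc2$variance_explained[1], 100, tolerance = 1e-9)
  # pipeline order enforced
  expect_error(pca_features(list(x = x)), "standardized")
})

test_that("UMAP embedding is deterministic and separates distant blobs", {
  set.seed(31)
  blobs <- rbind(matrix(rnorm(100 * 2, 0, 0.1), 100, 2),
                 matrix(rnorm(100 * 2, 10, 0.1), 100, 2))
  e1 <- umap_embed(blobs, seed = 9)
  e2 <- umap_embed(blobs, seed = 9)
  expect_identical(e1, e2)
  lab <- rep(1:2, each = 100)
  ctr <- rbind(colMeans(e1[lab == 1, ]), colMeans(e1[lab == 2, ]))
  inter <- sqrt(sum((ctr[1, ] - ctr[2, ])^2))
  r95 <- function(g) quantile(sqrt(rowSums(sweep(e1[lab == g, ], 2,
                                                 ctr[g, ], "-")^2)), 0.95)
  expect_gt(inter, r95(1))
  expect_gt(inter, r95(2))
  expect_error(umap_embed(blobs[1:10, ], n_neighbors = 15), "at least")
})

test_that("K-means finds the optimal partition of tight far-apart triads", {
  x <- rbind(matrix(rnorm(6, 0, 0.05), 3, 2),
             matrix(rnorm(6, 20, 0.05), 3, 2))
  km <- kmeans_clusters(x, k = 2, seed = 4, n_init = 20)
  expect_equal(km$tot_withinss, kmeans_wss_brute(x, 2), tolerance = 1e-9)
  expect_equal(length(unique(km$labels[1:3])), 1)
  expect_equal(length(unique(km$labels[4:6])), 1)
  # k = 1: centroid is the coordinate-wise mean
  km1 <- kmeans_clusters(x, k = 1, seed = 1)
  expect_equal(unname(km1$centroids[1, ]), unname(colMeans(x)))
  # determinism
  km2 <- kmeans_clusters(x, k = 2, seed = 4, n_init = 20)
  expect_identical(km$labels, km2$labels)
  expect_error(kmeans_clusters(x, k = 10, seed = 1), "between 1")
})

test_that("cluster labels are ordered by ascending mean of order_by", {
  set.seed(41)
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  ord <- c(rnorm(10, 100), rnorm(10, -100))
  km <- kmeans_clusters(x, 2, seed = 2, order_by = ord)
  # the group with the lower order_by mean gets label 1
  expect_true(all(km$labels[11:20] == 1))
  expect_true(all(km$labels[1:10] == 2))
})

test_that("frequency chi-square equals the formula oracle", {
  tab <- matrix(c(30, 25, 21, 10, 15, 20), 2, 3, byrow = TRUE)
  labels <- rep(rep(1:3, 2), times = c(t(tab)))
  groups <- rep(c("a", "b"), times = rowSums(tab))
  ft <- frequency_test(labels, groups)
  expect_equal(ft$chi2, chisq_brute(tab), tolerance = 1e-10)
  expect_equal(ft$df, 2)
  # identical distributions: chi2 = 0, p = 1
  l2 <- rep(1:3, times = c(10, 10, 10))
  ft2 <- frequency_test(c(l2, l2), rep(c("a", "b"), each = 30))
  expect_equal(ft2$chi2, 0)
  expect_equal(ft2$p, 1)
  expect_error(frequency_test(rep(1, 10), rep(c("a", "b"), 5)), "2 clusters")
  set.seed(51)
  for (i in 1:20) {
    tt <- matrix(rpois(6, 20) + 1, 2, 3)
    lab <- rep(rep(1:3, 2), times = c(t(tt)))
    grp <- rep(c("a", "b"), times = rowSums(tt))
    expect_equal(frequency_test(lab, grp)$chi2, chisq_brute(tt),
                 tolerance = 1e-10)
  }
})

test_that("D'Agostino-Pearson omnibus matches frozen reference values", {
  # reference values computed once with an independent implementation of
  # the same omnibus statistic (skewness + kurtosis normality test)
  x1 <- c(2.1, 3.4, 1.9, 5.6, 4.4, 3.3, 2.8, 4.1, 3.9, 2.2, 5.1, 3.7, 2.9,
          4.8, 3.1, 3.5, 4.2, 2.6, 3.8, 4.0)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$k2, 0.16374549219943646, tolerance = 1e-9)
  expect_equal(r1$p, 0.9213892016059635, tolerance = 1e-9)
  x2 <- round(exp(seq(0, 3, length.out = 25)), 3)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$k2, 5.219746008918502, tolerance = 1e-9)
  expect_equal(r2$p, 0.07354388291520882, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
  expect_error(dagostino_pearson(rep(3, 20)), "degenerate")
})

test_that("Dunn z-statistics square to the Kruskal-Wallis statistic for 2 groups", {
  set.seed(61)
  x <- c(rnorm(12), rnorm(12, 1))
  g <- rep(c("a", "b"), each = 12)
  dn <- dunn_test(x, g)
  kw <- kruskal.test(x, factor(g))
  expect_equal(dn$z^2, unname(kw$statistic), tolerance = 1e-9)
  expect_true(all(dn$p_adj >= dn$p - 1e-12 & dn$p_adj <= 1))
})

test_that("cluster comparisons pick the branch the normality gate dictates", {
  set.seed(71)
  # strongly non-normal values -> Kruskal-Wallis + Dunn branch
  xnn <- exp(rnorm(120, sd = 1.5))
  lab <- rep(1:3, each = 40)
  recs <- data.frame(cell_volume_um3 = xnn)
  out <- cluster_comparisons(recs, lab, features = "cell_volume_um3")
  expect_equal(out$cell_volume_um3$test, "kruskal_dunn")
  # clusters shifted by 3 SD: all pairwise comparisons significant
  xs <- c(rnorm(40, 0), rnorm(40, 3), rnorm(40, 6))
  out2 <- cluster_comparisons(data.frame(cell_volume_um3 = xs), lab,
                              features = "cell_volume_um3")
  expect_true(all(out2$cell_volume_um3$pairwise$p_adj < 0.05))
  # constant data: flagged, not tested
  out3 <- cluster_comparisons(data.frame(cell_volume_um3 = rep(1, 120)), lab,
                              features = "cell_volume_um3")
  expect_equal(out3$cell_volume_um3$test, "not_tested")
  # cluster below minimum size: flagged
  out4 <- cluster_comparisons(data.frame(cell_volume_um3 = rnorm(45)),
                              rep(c(1, 2, 3), times = c(40, 3, 2)),
                              features = "cell_volume_um3")
  expect_equal(out4$cell_volume_um3$test, "not_tested")
})

test_that("normality gate selects ANOVA at roughly the nominal rate", {
  set.seed(81)
  picks <- replicate(40, {
    x <- rnorm(180)
    dagostino_pearson(x)$p > 0.05
  })
  expect_gte(mean(picks), 0.8)
})

test_that("deterministic pipeline stages are permutation-equivariant", {
  set.seed(91)
  tab <- generate_feature_table(c(20, 20, 20), seed = 3)
  perm <- sample(nrow(tab))
  fm1 <- zscore_features(tab)
  fm2 <- zscore_features(tab[perm, ])
  expect_equal(unname(fm2$x), unname(fm1$x[perm, ]), tolerance = 1e-12)
  pc1 <- pca_features(fm1)
  pc2 <- pca_features(fm2)
  expect_equal(pc2$loading_matrix, pc1$loading_matrix, tolerance = 1e-9)
  expect_equal(unname(pc2$pc_scores), unname(pc1$pc_scores[perm, ]),
               tolerance = 1e-9)
})

test_that("silhouette scan prefers the true cluster count on clean blobs", {
  set.seed(95)
  x <- rbind(matrix(rnorm(60, 0, .3), 30, 2),
             matrix(rnorm(60, 6, .3), 30, 2),
             matrix(rnorm(60, c(12, 0), .3), 30, 2))
  sc <- silhouette_scan(x, ks = 2:5, seed = 1)
  expect_equal(sc$k[which.max(sc$avg_silhouette)], 3)
})
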