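# Subpopulation clustering: pooled Z-score, PCA, UMAP, K-means, cluster
# frequency chi-square and normality-gated per-cluster statistics. The
# pipeline order is fixed: normalization, then PCA, then UMAP, then K-means.

#' Names of the eight morphological parameters
#' @return character vector of the feature column names used throughout.
#' @export
morph_features <- function() {
  c("cell_volume_um3", "territory_um3", "ramification_index",
    "branchpoints", "endpoints", "avg_branch_um", "min_branch_um",
    "max_branch_um")
}

#' Pooled Z-score standardization
#'
#' Standardizes each parameter as z = (x - mu) / sigma with mu and sigma
#' computed over all rows pooled (never per group) and sigma the sample
#' (n - 1) standard deviation. Constant columns (sigma = 0) are set to zero
#' and reported via a warning. Rows with any missing parameter are dropped
#' with a message (degenerate-skeleton cells are the usual source).
#'
#' @param records data.frame containing the feature columns, plus optional
#'   `cell_id`, `animal_id`, `group` metadata carried through.
#' @param features feature column names; default [morph_features].
#' @return A `feature_matrix`: list with `x` (standardized matrix), `meta`
#'   (metadata data.frame), `mu`, `sigma`, `constant` (names of constant
#'   columns), `standardized = TRUE`.
#' @export
zscore_features <- function(records, features = morph_features()) {
  miss <- setdiff(features, names(records))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (nrow(records) < 2L) stop("need at least 2 rows to standardize")
  x <- as.matrix(records[, features, drop = FALSE])
  storage.mode(x) <- "double"
  ok <- complete.cases(x)
  if (!all(ok)) {
    message(sum(!ok), " row(s) with missing parameters dropped")
    records <- records[ok, , drop = FALSE]
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 complete rows to standardize")
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  constant <- names(sigma)[sigma == 0]
  if (length(constant))
    warning("constant column(s) set to zero: ", paste(constant, collapse = ", "))
  sig <- ifelse(sigma == 0, 1, sigma)
  z <- sweep(sweep(x, 2, mu, "-"), 2, sig, "/")
  z[, sigma == 0] <- 0
  meta_cols <- intersect(c("cell_id", "animal_id", "group", "archetype"),
                         names(records))
  structure(list(x = z, meta = records[, meta_cols, drop = FALSE],
                 mu = mu, sigma = sigma, constant = constant,
                 standardized = TRUE),
            class = "feature_matrix")
}

#' Principal component analysis of standardized features
#'
#' Eigen-decomposition of the pooled covariance matrix of the standardized
#' features (equal to the correlation matrix of the raw features).
#' Components are ordered by decreasing eigenvalue; the explained variance
#' of component i is 100 lambda_i / sum(lambda). Sign convention: the
#' largest-magnitude entry of each loading vector is positive.
#'
#' @param fm a `feature_matrix` from [zscore_features] (the pipeline order
#'   is fixed; unstandardized input is an error).
#' @param n_components number of components to return (default: all).
#' @return list with `loading_matrix` (parameters x n_components),
#'   `variance_explained` (percent per component over all components,
#'   summing to 100), `pc_scores` (cells x n_components).
#' @export
pca_features <- function(fm, n_components = NULL) {
  if (!inherits(fm, "feature_matrix") || !isTRUE(fm$standardized))
    stop("input must be a standardized feature_matrix (run zscore_features first)")
  x <- fm$x
  p <- ncol(x)
  if (is.null(n_components)) n_components <- p
  if (n_components < 1L || n_components > p)
    stop("n_components must be in 1..", p)
  cv <- crossprod(sweep(x, 2, colMeans(x), "-")) / (nrow(x) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  load <- eig$vectors
  for (j in seq_len(p)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(p))
  scores <- x %*% load
  list(loading_matrix = load[, seq_len(n_components), drop = FALSE],
       variance_explained = 100 * lam / sum(lam),
       pc_scores = scores[, seq_len(n_components), drop = FALSE])
}

#' UMAP embedding of PC scores
#'
#' Projects the PCA scores to 2D with uniform manifold approximation and
#' projection. Deterministic for a fixed seed (single-threaded optimization).
#'
#' @param pc_scores cells x components matrix.
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1).
#' @param seed RNG seed.
#' @param n_epochs optimization epochs; 200 is ample for datasets of a few
#'   hundred cells.
#' @return cells x 2 embedding matrix.
#' @export
umap_embed <- function(pc_scores, n_neighbors = 15L, min_dist = 0.1,
                       seed = 1L, n_epochs = 200L) {
  n <- nrow(pc_scores)
  if (n < n_neighbors + 1L)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1L, " rows, got ", n)
  set.seed(seed)
  emb <- uwot::umap(pc_scores, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_epochs = n_epochs, n_threads = 1, n_sgd_threads = 0,
                    verbose = FALSE)
  colnames(emb) <- c("UMAP1", "UMAP2")
  emb
}

#' K-means clustering of the embedding
#'
#' Best of `n_init` random initializations by within-cluster sum of squares.
#' Cluster ids are relabeled by ascending cluster mean of `order_by`
#' (normally the PC1 score) so that "cluster 1/2/3" is stable across seeds
#' and runs; with the default feature set this orders clusters from amoeboid
#' to ramified.
#'
#' @param embedding cells x d matrix (2D UMAP embedding, or PC scores).
#' @param k number of clusters (1 <= k <= n).
#' @param seed RNG seed.
#' @param n_init random restarts.
#' @param order_by numeric vector (length n) whose cluster means define the
#'   label order; default: first embedding column.
#' @return list with `labels` (integer 1..k per cell) and `centroids`
#'   (k x d).
#' @export
kmeans_clusters <- function(embedding, k, seed = 1L, n_init = 10L,
                            order_by = NULL) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k < 1L || k > n) stop("k must be between 1 and the number of cells")
  if (is.null(order_by)) order_by <- embedding[, 1]
  set.seed(seed)
  km <- kmeans(embedding, centers = k, nstart = n_init, iter.max = 100L)
  means <- tapply(order_by, km$cluster, mean)
  ord <- order(means)  # old label -> rank
  remap <- integer(k)
  remap[as.integer(names(means))[ord]] <- seq_len(k)
  labels <- remap[km$cluster]
  centroids <- km$centers[as.integer(names(means))[ord], , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  list(labels = labels, centroids = centroids,
       tot_withinss = km$tot.withinss)
}

#' Chi-square test of cluster frequencies between groups
#'
#' Pearson chi-square on the group x cluster contingency table, with
#' df = (r - 1)(c - 1). Expected counts are reported and cells with expected
#' count below 5 are flagged.
#'
#' @param labels cluster labels per cell.
#' @param group_labels group label per cell.
#' @return list with `chi2`, `df`, `p`, `table` (observed), `expected`,
#'   `low_expected` (logical matrix, expected < 5).
#' @export
frequency_test <- function(labels, group_labels) {
  tab <- table(group = group_labels, cluster = labels)
  if (nrow(tab) < 2L) stop("need at least 2 groups")
  if (ncol(tab) < 2L) stop("need at least 2 clusters")
  if (any(rowSums(tab) == 0L)) stop("empty group in contingency table")
  if (any(colSums(tab) == 0L)) stop("empty cluster in contingency table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, expected = ct$expected,
       low_expected = ct$expected < 5)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized skewness and kurtosis statistics into
#' K2 = Zs^2 + Zk^2, referred to a chi-square distribution with 2 df.
#' Requires n >= 8.
#'
#' @param x numeric vector.
#' @return list with `k2`, `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  if (sd(x) == 0) stop("degenerate sample: zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
             ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Dunn's post hoc test
#'
#' Pairwise rank-sum comparisons after a Kruskal-Wallis test: for each pair
#' of groups z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))
#' with tie correction T = sum(t^3 - t) / (12 (N - 1)), two-sided p-values
#' adjusted by Bonferroni (matching "Dunn's multiple comparisons").
#'
#' @param x numeric values.
#' @param g group labels.
#' @param p_adjust_method adjustment method, default "bonferroni".
#' @return data.frame with `comparison`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g, p_adjust_method = "bonferroni") {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tiecor <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ni <- table(g)
  lev <- levels(g)
  pairs <- combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  cmp <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tiecor) * (1 / ni[[i]] + 1 / ni[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
    cmp[k] <- paste(i, "vs", j)
  }
  data.frame(comparison = cmp, z = z, p = p,
             p_adj = pmin(1, p.adjust(p, method = p_adjust_method)),
             stringsAsFactors = FALSE)
}

#' Per-cluster parameter comparisons with a normality gate
#'
#' For each parameter, pooled values are tested for normality with the
#' D'Agostino-Pearson omnibus test. Normal parameters are compared across
#' clusters with ordinary one-way ANOVA followed by Bonferroni-adjusted
#' pairwise t tests (pooled SD); non-normal parameters with Kruskal-Wallis
#' followed by Dunn's multiple comparisons. Parameters for which any cluster
#' has fewer than `min_cluster_size` cells (or with degenerate pooled
#' variance) are flagged and not tested.
#'
#' @param records data.frame with the feature columns.
#' @param labels cluster label per row.
#' @param features parameter columns; default [morph_features].
#' @param alpha normality-gate significance level (default 0.05: p above
#'   alpha selects the parametric branch).
#' @param min_cluster_size minimum cells per cluster (default 3).
#' @return named list per parameter: `test` ("anova_bonferroni",
#'   "kruskal_dunn" or "not_tested"), `normality_p`, `omnibus_statistic`,
#'   `omnibus_p`, `pairwise` (data.frame with adjusted p-values), `note`.
#' @export
cluster_comparisons <- function(records, labels, features = morph_features(),
                                alpha = 0.05, min_cluster_size = 3L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 clusters")
  out <- list()
  for (f in features) {
    x <- records[[f]]
    sizes <- table(labels[is.finite(x)])
    if (any(sizes < min_cluster_size)) {
      out[[f]] <- list(test = "not_tested", normality_p = NA_real_,
                       omnibus_statistic = NA_real_, omnibus_p = NA_real_,
                       pairwise = NULL,
                       note = "cluster below minimum size")
      next
    }
    if (sd(x, na.rm = TRUE) == 0) {
      out[[f]] <- list(test = "not_tested", normality_p = NA_real_,
                       omnibus_statistic = NA_real_, omnibus_p = NA_real_,
                       pairwise = NULL,
                       note = "degenerate: constant values")
      next
    }
    norm <- try(dagostino_pearson(x), silent = TRUE)
    if (inherits(norm, "try-error")) {
      out[[f]] <- list(test = "not_tested", normality_p = NA_real_,
                       omnibus_statistic = NA_real_, omnibus_p = NA_real_,
                       pairwise = NULL, note = "normality test degenerate")
      next
    }
    if (norm$p > alpha) {
      fit <- aov(x ~ labels)
      an <- summary(fit)[[1]]
      pw <- stats::pairwise.t.test(x, labels, p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)
      pm <- pw$p.value
      cmp <- character(0); padj <- numeric(0)
      for (i in rownames(pm)) for (j in colnames(pm))
        if (!is.na(pm[i, j])) {
          cmp <- c(cmp, paste(j, "vs", i)); padj <- c(padj, pm[i, j])
        }
      out[[f]] <- list(test = "anova_bonferroni",
                       normality_p = norm$p,
                       omnibus_statistic = an$`F value`[1],
                       omnibus_p = an$`Pr(>F)`[1],
                       pairwise = data.frame(comparison = cmp, p_adj = padj,
                                             stringsAsFactors = FALSE),
                       note = "")
    } else {
      kw <- kruskal.test(x, labels)
      dn <- dunn_test(x, labels)
      out[[f]] <- list(test = "kruskal_dunn",
                       normality_p = norm$p,
                       omnibus_statistic = unname(kw$statistic),
                       omnibus_p = kw$p.value,
                       pairwise = dn[, c("comparison", "z", "p_adj")],
                       note = "")
    }
  }
  out
}

#' Run the full clustering pipeline
#'
#' Fixed order: pooled Z-score normalization, PCA, UMAP of the PC scores,
#' K-means in the reduced space. By default K-means runs on the 2D UMAP
#' embedding; `cluster_space = "pca"` clusters the PC scores directly as a
#' sensitivity analysis. Cluster ids are stabilized by ascending cluster
#' mean PC1.
#'
#' @param records feature data.frame (e.g. from [measure_cells] or
#'   [generate_feature_table]).
#' @param config config list; uses `k`, `n_init`, `umap_n_neighbors`,
#'   `umap_min_dist`, `cluster_space`, `seed`.
#' @param features feature columns.
#' @return list with `feature_matrix`, `pca`, `embedding`, `labels`,
#'   `centroids`, `frequency` (chi-square result if >= 2 groups present,
#'   else NULL), and `params` echoing all hyperparameters and seeds.
#' @export
cluster_pipeline <- function(records, config = default_config(),
                             features = morph_features()) {
  fm <- zscore_features(records, features)
  pc <- pca_features(fm)
  emb <- umap_embed(pc$pc_scores, n_neighbors = config$umap_n_neighbors,
                    min_dist = config$umap_min_dist, seed = config$seed,
                    n_epochs = config$umap_n_epochs)
  space <- if (identical(config$cluster_space, "pca")) pc$pc_scores else emb
  km <- kmeans_clusters(space, k = config$k, seed = config$seed,
                        n_init = config$n_init, order_by = pc$pc_scores[, 1])
  freq <- NULL
  if ("group" %in% names(fm$meta) && length(unique(fm$meta$group)) >= 2L &&
      config$k >= 2L)
    freq <- frequency_test(km$labels, fm$meta$group)
  list(feature_matrix = fm, pca = pc, embedding = emb,
       labels = km$labels, centroids = km$centroids, frequency = freq,
       params = list(k = config$k, n_init = config$n_init,
                     umap_n_neighbors = config$umap_n_neighbors,
                     umap_min_dist = config$umap_min_dist,
                     umap_n_epochs = config$umap_n_epochs,
                     cluster_space = config$cluster_space,
                     seed = config$seed))
}

#' Silhouette scan over candidate cluster counts
#'
#' Average silhouette width of K-means partitions for each candidate k,
#' computed on the clustering space; a simple aid for choosing k when it is
#' not fixed a priori.
#'
#' @param embedding cells x d matrix.
#' @param ks candidate cluster counts (default 2:6).
#' @param seed,n_init as in [kmeans_clusters].
#' @return data.frame with `k` and `avg_silhouette`.
#' @export
silhouette_scan <- function(embedding, ks = 2:6, seed = 1L, n_init = 10L) {
  embedding <- as.matrix(embedding)
  dm <- as.matrix(dist(embedding))
  avg_sil <- vapply(ks, function(k) {
    km <- kmeans_clusters(embedding, k, seed = seed, n_init = n_init)
    lab <- km$labels
    s <- vapply(seq_len(nrow(embedding)), function(i) {
      own <- lab == lab[i]; own[i] <- FALSE
      a <- if (any(own)) mean(dm[i, own]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(cl) mean(dm[i, lab == cl]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }, numeric(1))
  data.frame(k = ks, avg_silhouette = avg_sil)
}
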