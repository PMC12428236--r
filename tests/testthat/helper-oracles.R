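# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Otsu: exhaustive scan of between-class variance over all candidate levels,
# straight from the definition (background <= t, foreground > t).
otsu_brute <- function(counts, levels = seq_along(counts) - 1L) {
  n <- sum(counts)
  mu_t <- sum(counts * levels) / n
  best <- -Inf; best_t <- levels[1]
  for (t in levels) {
    sel <- levels <= t
    w0 <- sum(counts[sel]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) { s <- 0 }
    else {
      mu0 <- sum(counts[sel] * levels[sel]) / sum(counts[sel])
      mu1 <- sum(counts[!sel] * levels[!sel]) / sum(counts[!sel])
      s <- w0 * w1 * (mu0 - mu1)^2
    }
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# convex hull volume by facet enumeration: for points in general position,
# every hull facet is a triple whose plane has all other points on one side;
# the volume is the sum of signed tetrahedra against the centroid.
hull_volume_brute <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
    nrm <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
             (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
             (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    d <- as.vector((pts[-tri, , drop = FALSE] %*% nrm) - sum(nrm * a))
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      # orient outward relative to centroid and add the signed tet volume
      s <- sum(nrm * (a - ctr))
      h <- abs(det(rbind(a - ctr, b - ctr, c - ctr))) / 6
      vol <- vol + h
    }
  }
  vol
}

# connected-component count by flood fill over an adjacency built from
# scratch (no package labeling code)
count_components_brute <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  co <- arrayInd(idx, d)
  key <- function(z, y, x) paste(z, y, x)
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(idx)) assign(key(co[i, 1], co[i, 2], co[i, 3]), i, lookup)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  seen <- logical(length(idx))
  comps <- 0L
  for (i in seq_along(idx)) {
    if (seen[i]) next
    comps <- comps + 1L
    stack <- i; seen[i] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (r in seq_len(nrow(offs))) {
        k <- key(co[cur, 1] + offs[r, 1], co[cur, 2] + offs[r, 2],
                 co[cur, 3] + offs[r, 3])
        j <- mget(k, lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
      }
    }
  }
  comps
}

# exhaustive K-means: minimal within-cluster sum of squares over all
# assignments of n points to k labels
kmeans_wss_brute <- function(x, k) {
  n <- nrow(x)
  grids <- rep(list(seq_len(k)), n)
  best <- Inf
  assign_grid <- do.call(expand.grid, grids)
  for (r in seq_len(nrow(assign_grid))) {
    lab <- as.integer(assign_grid[r, ])
    if (length(unique(lab)) < k) next
    wss <- 0
    for (g in unique(lab)) {
      xs <- x[lab == g, , drop = FALSE]
      wss <- wss + sum(sweep(xs, 2, colMeans(xs), "-")^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) labelings
mw_exact_brute <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(sel)
    sum(rank(pooled)[sel]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Pearson chi-square straight from the definition
chisq_brute <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# small geometric phantom masks ------------------------------------------

make_ball_mask <- function(r_vox = 8L, pad = 3L) {
  n <- 2L * (r_vox + pad) + 1L
  c0 <- r_vox + pad + 1L
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  m <- array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r_vox^2, c(n, n, n))
  m
}

# axis-aligned rod along +x starting at the center voxel
make_rod_mask <- function(len_vox = 61L, r_vox = 2L, pad = 4L) {
  nz <- 2L * (r_vox + pad) + 1L
  c0 <- r_vox + pad + 1L
  nx <- len_vox + 2L * pad
  m <- array(FALSE, c(nz, nz, nx))
  for (x in pad + seq_len(len_vox))
    for (z in 1:nz) for (y in 1:nz)
      if ((z - c0)^2 + (y - c0)^2 <= r_vox^2) m[z, y, x] <- TRUE
  m
}

# Y: stem along +x then two arms at +-45 degrees in the x-y plane
make_y_mask <- function(stem_vox = 21L, arm_vox = 29L, r_vox = 2L, pad = 5L) {
  n <- stem_vox + arm_vox + 2L * pad
  ny <- 2L * (arm_vox + pad) + 2L * r_vox
  nz <- 2L * (r_vox + pad) + 1L
  cz <- r_vox + pad + 1L
  cy <- ny %/% 2L
  m <- array(FALSE, c(nz, ny, n))
  fill_cap <- function(m, A, B, r) {
    for (x in 1:dim(m)[3]) for (y in 1:dim(m)[2]) for (z in 1:dim(m)[1]) {
      p <- c(z, y, x); d <- B - A; L2 <- sum(d^2)
      t <- max(0, min(1, sum((p - A) * d) / L2))
      if (sum((p - (A + t * d))^2) <= r^2) m[z, y, x] <- TRUE
    }
    m
  }
  A <- c(cz, cy, pad + 1)
  Bj <- c(cz, cy, pad + stem_vox)
  m <- fill_cap(m, A, Bj, r_vox)
  arm <- round(arm_vox / sqrt(2))
  m <- fill_cap(m, Bj, Bj + c(0, arm, arm), r_vox)
  m <- fill_cap(m, Bj, Bj + c(0, -arm, arm), r_vox)
  m
}

first_cell <- function(mask, spacing = c(1, 1, 1)) {
  extract_cells(label_mask(mask, spacing = spacing))[[1]]
}
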