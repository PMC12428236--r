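# Synthetic phantoms: soma-plus-branching-tube cells rendered into voxel
# stacks with exact ground-truth topology, and tabular feature mixtures with
# known cluster labels. Capsule (cylinder + hemispherical cap) rendering is
# used so analytic volumes exist for checks.

#' Archetype defaults for phantom cells
#'
#' Morphology presets emulating the classical microglial spectrum: compact
#' amoeboid cells with at most stub processes, intermediate cells, and
#' ramified cells with deep branching trees. Geometry is in micrometres;
#' radii and segment lengths are in the range reported for rodent microglia
#' (soma radius 3-4 um, process radius under 1 um, inter-branch segments of
#' a few micrometres).
#'
#' @param archetype one of "amoeboid", "intermediate", "ramified".
#' @return A named list of [phantom_spec] geometry fields.
#' @export
archetype_defaults <- function(archetype) {
  switch(match.arg(archetype, c("amoeboid", "intermediate", "ramified")),
    amoeboid = list(soma_radius = 3.5, n_primary_branches = 3L,
                    max_branch_depth = 1L, bifurcation_prob = 0,
                    branch_len_mean = 5, branch_len_sd = 1.5,
                    branch_radius = 0.8, tortuosity = 0.25),
    intermediate = list(soma_radius = 3.5, n_primary_branches = 3L,
                        max_branch_depth = 2L, bifurcation_prob = 0.3,
                        branch_len_mean = 7, branch_len_sd = 2,
                        branch_radius = 0.7, tortuosity = 0.25),
    ramified = list(soma_radius = 3.0, n_primary_branches = 4L,
                    max_branch_depth = 3L, bifurcation_prob = 0.4,
                    branch_len_mean = 7, branch_len_sd = 2,
                    branch_radius = 0.6, tortuosity = 0.25))
}

#' Phantom cell specification
#'
#' @param archetype "amoeboid", "intermediate" or "ramified"; sets geometry
#'   defaults via [archetype_defaults], individually overridable.
#' @param soma_radius soma ball radius, um (> branch_radius).
#' @param n_primary_branches processes leaving the soma.
#' @param max_branch_depth maximal number of segments along any root-to-tip
#'   path (amoeboid <= 1, ramified >= 3).
#' @param bifurcation_prob probability that a growing tip bifurcates at each
#'   segment end (before reaching max depth).
#' @param branch_len_mean,branch_len_sd segment length distribution, um.
#' @param branch_radius process tube radius, um.
#' @param tortuosity SD of the per-segment direction perturbation, radians.
#' @param foreground_level,background_level rendered intensities (8-bit).
#' @param noise_sd additive Gaussian noise SD in intensity units; the
#'   signal-to-noise ratio is (foreground - background) / noise_sd.
#' @param seed per-cell RNG seed for tree growth.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(archetype = "ramified",
                         soma_radius = NULL, n_primary_branches = NULL,
                         max_branch_depth = NULL, bifurcation_prob = NULL,
                         branch_len_mean = NULL, branch_len_sd = NULL,
                         branch_radius = NULL, tortuosity = NULL,
                         foreground_level = 120, background_level = 10,
                         noise_sd = 0, seed = 1L) {
  archetype <- match.arg(archetype, c("amoeboid", "intermediate", "ramified"))
  def <- archetype_defaults(archetype)
  pick <- function(x, d) if (is.null(x)) d else x
  sp <- list(
    archetype = archetype,
    soma_radius = pick(soma_radius, def$soma_radius),
    n_primary_branches = as.integer(pick(n_primary_branches, def$n_primary_branches)),
    max_branch_depth = as.integer(pick(max_branch_depth, def$max_branch_depth)),
    bifurcation_prob = pick(bifurcation_prob, def$bifurcation_prob),
    branch_len_mean = pick(branch_len_mean, def$branch_len_mean),
    branch_len_sd = pick(branch_len_sd, def$branch_len_sd),
    branch_radius = pick(branch_radius, def$branch_radius),
    tortuosity = pick(tortuosity, def$tortuosity),
    foreground_level = foreground_level,
    background_level = background_level,
    noise_sd = noise_sd,
    seed = as.integer(seed))
  if (!(sp$soma_radius > sp$branch_radius && sp$branch_radius > 0))
    stop("need soma_radius > branch_radius > 0")
  if (sp$archetype == "amoeboid" && sp$max_branch_depth > 1L)
    stop("amoeboid phantoms have max_branch_depth <= 1")
  if (sp$archetype == "ramified" && sp$max_branch_depth < 3L)
    stop("ramified phantoms have max_branch_depth >= 3")
  if (sp$bifurcation_prob < 0 || sp$bifurcation_prob > 1)
    stop("bifurcation_prob must be in [0, 1]")
  structure(sp, class = "phantom_spec")
}

# rotate v by angle around unit axis (Rodrigues)
rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}
random_perp <- function(dir) {
  repeat {
    u <- pracma_cross(dir, random_unit())
    n <- sqrt(sum(u^2))
    if (n > 1e-6) return(u / n)
  }
}

# min distance from point p to segment AB
point_seg_dist <- function(p, A, B) {
  d <- B - A
  L2 <- sum(d^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - A) * d) / L2))
  sqrt(sum((p - (A + t * d))^2))
}

# exact minimum distance between segments AB and CD (Ericson, Real-Time
# Collision Detection 5.1.9)
seg_seg_dist <- function(A, B, C, D) {
  d1 <- B - A; d2 <- D - C; r <- A - C
  a <- sum(d1^2); e <- sum(d2^2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r^2)))
  if (a <= 1e-12) {
    t <- min(1, max(0, f / e))
    return(sqrt(sum((A - (C + t * d2))^2)))
  }
  cc <- sum(d1 * r)
  if (e <= 1e-12) {
    s <- min(1, max(0, -cc / a))
    return(sqrt(sum(((A + s * d1) - C)^2)))
  }
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-12) min(1, max(0, (b * f - cc * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(1, max(0, -cc / a)) }
  else if (t > 1) { t <- 1; s <- min(1, max(0, (b - cc) / a)) }
  sqrt(sum(((A + s * d1) - (C + t * d2))^2))
}

# Grow one tree (cell-local physical coordinates, soma center at origin).
# Uses the current RNG stream; callers seed it.
grow_tree <- function(spec, clearance_extra = 1.0) {
  nodes <- matrix(0, 1, 3)       # node 1 = soma center
  seg_from <- integer(0); seg_to <- integer(0); seg_depth <- integer(0)
  clearance <- 2 * spec$branch_radius + clearance_extra

  collides <- function(A, B, skip_nodes) {
    # never grow back into the soma (only primaries leave it); the near-A
    # fifth of the candidate is exempt so branching near the soma surface
    # is not rejected for its own origin
    if (!(1L %in% skip_nodes) &&
        point_seg_dist(c(0, 0, 0), A + 0.2 * (B - A), B) <
        spec$soma_radius + clearance) return(TRUE)
    for (s in seq_along(seg_from)) {
      # ignore segments sharing a node with the candidate (parent, siblings)
      if (seg_from[s] %in% skip_nodes || seg_to[s] %in% skip_nodes) next
      if (seg_seg_dist(A, B, nodes[seg_from[s], ], nodes[seg_to[s], ]) < clearance)
        return(TRUE)
    }
    FALSE
  }

  # segments must stay resolvable: a measured skeleton branch is shorter
  # than the true branch by the thinning tip erosion (~2-3 voxels), the cap
  # radius and the junction-cluster offset, about 3.5 um in total at 0.5 um
  # sampling, and branches measuring under the 2 um spur threshold are
  # pruned; generated segments are therefore truncated at 5.5 um so that
  # every true branch is above the resolvability limit of the measurement
  draw_len <- function() max(5.5, rnorm(1, spec$branch_len_mean, spec$branch_len_sd))

  add_segment <- function(from_node, dir, depth) {
    for (try in 1:20) {
      # primaries run from the soma center to soma_radius + L so that every
      # recorded process actually protrudes L micrometres beyond the soma
      L <- draw_len() + if (from_node == 1L) spec$soma_radius else 0
      B <- nodes[from_node, ] + L * dir
      if (!collides(nodes[from_node, ], B, skip_nodes = from_node)) {
        nodes <<- rbind(nodes, B)
        nb <- nrow(nodes)
        seg_from <<- c(seg_from, from_node)
        seg_to <<- c(seg_to, nb)
        seg_depth <<- c(seg_depth, depth)
        return(nb)
      }
      dir <- rotate_about(dir, random_perp(dir), rnorm(1, 0, 0.5))
      dir <- dir / sqrt(sum(dir^2))
    }
    NA_integer_  # give up: branch terminates early
  }

  # spread primary directions (min pairwise separation keeps processes apart)
  min_sep <- if (spec$n_primary_branches <= 4L) 70 else 50  # degrees
  prim <- list()
  for (i in seq_len(spec$n_primary_branches)) {
    placed <- FALSE
    for (try in 1:500) {
      d <- random_unit()
      ok <- all(vapply(prim, function(p)
        acos(pmin(1, pmax(-1, sum(p * d)))) * 180 / pi >= min_sep, logical(1)))
      if (ok) { prim[[length(prim) + 1L]] <- d; placed <- TRUE; break }
    }
    if (!placed) prim[[length(prim) + 1L]] <- random_unit()
  }

  # active tips: (node, direction, depth)
  tips <- list()
  for (d in prim) {
    nb <- add_segment(1L, d, 1L)
    if (!is.na(nb)) tips[[length(tips) + 1L]] <- list(node = nb, dir = d, depth = 1L)
  }
  while (length(tips)) {
    tip <- tips[[1]]; tips[[1]] <- NULL
    if (tip$depth >= spec$max_branch_depth) next
    if (runif(1) < spec$bifurcation_prob) {
      # resample until the two daughters keep at least 45 degrees between
      # them (after the tortuosity perturbation), so sibling tubes diverge
      axis <- random_perp(tip$dir)
      for (try in 1:20) {
        ds <- lapply(c(1, -1), function(sgn) {
          ang <- (30 + runif(1, 0, 20)) * pi / 180
          d2 <- rotate_about(tip$dir, axis, sgn * ang)
          d2 <- rotate_about(d2, random_perp(d2), rnorm(1, 0, spec$tortuosity))
          d2 / sqrt(sum(d2^2))
        })
        sep <- acos(pmin(1, pmax(-1, sum(ds[[1]] * ds[[2]])))) * 180 / pi
        if (sep >= 45) break
      }
      for (d2 in ds) {
        nb <- add_segment(tip$node, d2, tip$depth + 1L)
        if (!is.na(nb)) tips[[length(tips) + 1L]] <- list(node = nb, dir = d2,
                                                          depth = tip$depth + 1L)
      }
    } else {
      d2 <- rotate_about(tip$dir, random_perp(tip$dir), rnorm(1, 0, spec$tortuosity))
      d2 <- d2 / sqrt(sum(d2^2))
      nb <- add_segment(tip$node, d2, tip$depth + 1L)
      if (!is.na(nb)) tips[[length(tips) + 1L]] <- list(node = nb, dir = d2,
                                                        depth = tip$depth + 1L)
    }
  }
  list(nodes = nodes, seg_from = seg_from, seg_to = seg_to,
       seg_depth = seg_depth)
}

# Condensed ground-truth topology of a grown tree. Terminal tips are
# extended by the capsule cap (branch_radius) because the rendered process
# physically reaches that far; the skeleton of the rendered cell does too.
tree_truth <- function(tree, spec) {
  nn <- nrow(tree$nodes)
  deg <- tabulate(c(tree$seg_from, tree$seg_to), nbins = nn)
  children <- tabulate(tree$seg_from, nbins = nn)
  nodes <- tree$nodes
  if (length(tree$seg_from)) {
    term <- which(deg == 1L & seq_len(nn) != 1L)
    for (t in term) {
      s <- which(tree$seg_to == t)
      d <- nodes[t, ] - nodes[tree$seg_from[s], ]
      nodes[t, ] <- nodes[t, ] + spec$branch_radius * d / sqrt(sum(d^2))
    }
  }
  seg_len <- if (length(tree$seg_from))
    sqrt(rowSums((nodes[tree$seg_to, , drop = FALSE] -
                  nodes[tree$seg_from, , drop = FALSE])^2)) else numeric(0)

  if (nn == 1L)
    return(list(branchpoints = 0L, endpoints = 0L, branch_lengths_um = numeric(0),
                degenerate = TRUE, nodes = nodes, seg_len = seg_len))

  critical <- deg == 1L | deg >= 3L
  adj <- vector("list", nn)
  for (s in seq_along(tree$seg_from)) {
    i <- tree$seg_from[s]; j <- tree$seg_to[s]
    adj[[i]] <- rbind(adj[[i]], c(j, s))
    adj[[j]] <- rbind(adj[[j]], c(i, s))
  }
  seen <- logical(length(tree$seg_from))
  lens <- numeric(0)
  for (u in which(critical)) {
    if (is.null(adj[[u]])) next
    for (r in seq_len(nrow(adj[[u]]))) {
      v <- adj[[u]][r, 1]; s <- adj[[u]][r, 2]
      if (seen[s]) next
      seen[s] <- TRUE
      len <- seg_len[s]; prev <- u; cur <- v
      while (!critical[cur]) {
        nb <- adj[[cur]]
        nxt <- nb[nb[, 1] != prev, , drop = FALSE]
        if (!nrow(nxt)) break
        seen[nxt[1, 2]] <- TRUE
        len <- len + seg_len[nxt[1, 2]]
        prev <- cur; cur <- nxt[1, 1]
      }
      lens <- c(lens, len)
    }
  }
  list(branchpoints = sum(deg >= 3L),
       endpoints = sum(deg == 1L),
       branch_lengths_um = lens,
       degenerate = FALSE,
       nodes = nodes, seg_len = seg_len)
}

fill_ball <- function(mask, center, R, spacing) {
  d <- dim(mask)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor((center[a] - R) / spacing[a]) + 1L)
    hi <- min(d[a], ceiling((center[a] + R) / spacing[a]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(vapply(rng, length, integer(1)) == 0L)) return(mask)
  dz2 <- ((rng[[1]] - 1) * spacing[1] - center[1])^2
  dy2 <- ((rng[[2]] - 1) * spacing[2] - center[2])^2
  dx2 <- ((rng[[3]] - 1) * spacing[3] - center[3])^2
  box <- outer(outer(dz2, dy2, "+"), dx2, "+") <= R^2
  mask[rng[[1]], rng[[2]], rng[[3]]] <- mask[rng[[1]], rng[[2]], rng[[3]]] | box
  mask
}

fill_capsule <- function(mask, A, B, r, spacing) {
  d <- dim(mask)
  lo <- pmin(A, B) - r; hi <- pmax(A, B) + r
  rng <- lapply(1:3, function(a) {
    l <- max(1L, floor(lo[a] / spacing[a]) + 1L)
    h <- min(d[a], ceiling(hi[a] / spacing[a]) + 1L)
    if (l > h) integer(0) else l:h
  })
  if (any(vapply(rng, length, integer(1)) == 0L)) return(mask)
  g <- expand.grid(z = (rng[[1]] - 1) * spacing[1],
                   y = (rng[[2]] - 1) * spacing[2],
                   x = (rng[[3]] - 1) * spacing[3])
  P <- as.matrix(g)[, c("z", "y", "x")]
  dvec <- B - A
  L2 <- sum(dvec^2)
  t <- if (L2 == 0) rep(0, nrow(P)) else
    pmin(1, pmax(0, (sweep(P, 2, A, "-") %*% dvec) / L2))
  proj <- sweep(t %*% t(dvec), 2, A, "+")
  ok <- rowSums((P - proj)^2) <= r^2
  box <- array(ok, vapply(rng, length, integer(1)))
  mask[rng[[1]], rng[[2]], rng[[3]]] <- mask[rng[[1]], rng[[2]], rng[[3]]] | box
  mask
}

#' Generate a phantom stack with ground truth
#'
#' Renders each spec as a soma ball plus a random tree of capsule segments:
#' from each active tip growth continues with its direction perturbed by the
#' tortuosity, bifurcating with `bifurcation_prob` until the maximum depth.
#' A segment that cannot be placed without touching a non-adjacent segment
#' (minimum clearance of one tube diameter plus one micrometre) terminates
#' its branch, so rendered cells are collision-free and the recorded topology
#' is exact. Constant background and optional shot-noise-like Gaussian noise
#' (SD proportional to the square root of the signal, `noise_sd` at the
#' foreground plateau) are added and the stack is quantized to 8 bits.
#' Deterministic for fixed seeds.
#'
#' @param specs a [phantom_spec] or list of them.
#' @param grid_shape optional (nz, ny, nx); when `NULL` the grid is sized to
#'   fit the cells, laid out along x. When given, cell centers are placed by
#'   rejection sampling with non-overlapping territories (error after 1000
#'   failed attempts).
#' @param spacing voxel spacing (dz, dy, dx), um; default 0.5 um isotropic.
#' @param placement_seed seed for placement and noise.
#' @param margin empty margin around each cell, um.
#' @return list with `grid` (a [voxel_grid], 8-bit), `labels` (integer array,
#'   the voxelized true mask, one label per cell), and `truth` (per-cell
#'   list: archetype, branchpoints, endpoints, branch_lengths_um,
#'   soma_center, soma_volume_um3, cell_volume_um3_analytic, center).
#' @export
generate_phantom_stack <- function(specs, grid_shape = NULL,
                                   spacing = c(0.5, 0.5, 0.5),
                                   placement_seed = 1L, margin = 2) {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  spacing <- as.numeric(spacing)

  trees <- vector("list", length(specs))
  truths <- vector("list", length(specs))
  extents <- numeric(length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    set.seed(sp$seed)
    trees[[i]] <- grow_tree(sp)
    truths[[i]] <- tree_truth(trees[[i]], sp)
    extents[i] <- max(sqrt(rowSums(truths[[i]]$nodes^2))) +
      max(sp$soma_radius, sp$branch_radius)
  }

  set.seed(placement_seed)
  if (is.null(grid_shape)) {
    # tight per-axis field of view around each cell (as when cropping a
    # single cell for analysis), cells laid out along x
    pads <- vapply(specs, function(sp)
      max(sp$soma_radius, sp$branch_radius) + margin, numeric(1))
    los <- t(vapply(seq_along(specs), function(i)
      apply(truths[[i]]$nodes, 2, min) - pads[i], numeric(3)))
    his <- t(vapply(seq_along(specs), function(i)
      apply(truths[[i]]$nodes, 2, max) + pads[i], numeric(3)))
    spans <- his - los
    hz <- max(spans[, 1]); hy <- max(spans[, 2])
    widths <- spans[, 3]
    dims <- c(ceiling(hz / spacing[1]) + 1L,
              ceiling(hy / spacing[2]) + 1L,
              ceiling(sum(widths) / spacing[3]) + 1L)
    centers <- matrix(0, length(specs), 3)
    xoff <- 0
    for (i in seq_along(specs)) {
      centers[i, ] <- c(-los[i, 1] + (hz - spans[i, 1]) / 2,
                        -los[i, 2] + (hy - spans[i, 2]) / 2,
                        xoff - los[i, 3])
      xoff <- xoff + widths[i]
    }
  } else {
    dims <- as.integer(grid_shape)
    phys <- (dims - 1L) * spacing
    centers <- matrix(0, length(specs), 3)
    for (i in seq_along(specs)) {
      placed <- FALSE
      for (try in 1:1000) {
        cand <- vapply(1:3, function(a) {
          lo <- extents[i] + margin; hi <- phys[a] - extents[i] - margin
          if (hi < lo) NA_real_ else runif(1, lo, hi)
        }, numeric(1))
        if (anyNA(cand)) stop("grid too small to place cell ", i)
        ok <- TRUE
        if (i > 1) for (j in 1:(i - 1))
          if (sqrt(sum((cand - centers[j, ])^2)) <
              extents[i] + extents[j] + margin) { ok <- FALSE; break }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("could not place cell ", i, " after 1000 attempts")
    }
  }

  labels <- array(0L, dims)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    tr <- trees[[i]]
    mask <- array(FALSE, dims)
    ctr <- centers[i, ]
    mask <- fill_ball(mask, ctr, sp$soma_radius, spacing)
    for (s in seq_along(tr$seg_from))
      mask <- fill_capsule(mask,
                           ctr + tr$nodes[tr$seg_from[s], ],
                           ctr + tr$nodes[tr$seg_to[s], ],
                           sp$branch_radius, spacing)
    labels[mask] <- i
    truths[[i]] <- c(truths[[i]][c("branchpoints", "endpoints",
                                   "branch_lengths_um", "degenerate")],
                     list(archetype = sp$archetype,
                          soma_center = ctr,
                          soma_volume_um3 = 4 / 3 * pi * sp$soma_radius^3,
                          cell_volume_um3_analytic =
                            4 / 3 * pi * sp$soma_radius^3 +
                            sum(pi * sp$branch_radius^2 * truths[[i]]$seg_len),
                          center = ctr))
  }

  sp1 <- specs[[1]]
  vals <- array(sp1$background_level, dims)
  for (i in seq_along(specs))
    vals[labels == i] <- specs[[i]]$foreground_level
  if (sp1$noise_sd > 0) {
    # Gaussian approximation to photon shot noise: the SD scales with the
    # square root of the signal and noise_sd is the SD at the foreground
    # plateau, so SNR = (foreground - background) / noise_sd
    sd_vox <- sp1$noise_sd * sqrt(pmax(vals, 1) / sp1$foreground_level)
    vals <- vals + rnorm(length(vals), 0, 1) * sd_vox
  }
  vals <- array(as.integer(pmin(255, pmax(0, round(vals)))), dims)

  list(grid = voxel_grid(vals, spacing, source_id = "phantom"),
       labels = labels, truth = truths)
}

#' Default feature-mixture parameters for the three archetypes
#'
#' Mean and SD of the eight morphological parameters per archetype, chosen
#' so that archetype centers are separated by at least two pooled SDs on the
#' dominant parameters (territory, ramification index, branch counts), as
#' required for a well-posed clustering recovery benchmark.
#'
#' @return list with matrices `means` and `sds` (3 archetypes x 8 parameters).
#' @export
feature_archetype_params <- function() {
  p <- c("cell_volume_um3", "territory_um3", "ramification_index",
         "branchpoints", "endpoints", "avg_branch_um", "min_branch_um",
         "max_branch_um")
  a <- c("amoeboid", "intermediate", "ramified")
  means <- matrix(c(
    500, 1200, 2.4, 2, 4, 5, 2.5, 8,
    700, 5000, 7.0, 8, 11, 7, 3.0, 14,
    900, 14000, 16.0, 18, 21, 9, 3.5, 20), 3, 8, byrow = TRUE,
    dimnames = list(a, p))
  sds <- matrix(c(
    100, 400, 0.7, 1.2, 1.5, 1.2, 0.8, 2,
    120, 1200, 1.8, 2.5, 2.8, 1.5, 0.9, 3,
    150, 3000, 3.5, 4.0, 4.5, 1.8, 1.0, 4), 3, 8, byrow = TRUE,
    dimnames = list(a, p))
  list(means = means, sds = sds)
}

draw_archetype_features <- function(archetypes, means, sds) {
  out <- matrix(NA_real_, length(archetypes), ncol(means),
                dimnames = list(NULL, colnames(means)))
  for (i in seq_along(archetypes)) {
    a <- archetypes[i]
    out[i, ] <- rnorm(ncol(means), means[a, ], sds[a, ])
  }
  out
}

#' Generate a feature table with known archetype labels
#'
#' Draws cells from per-archetype multivariate normals with diagonal
#' covariance. Row counts per archetype are exact; group labels split each
#' archetype evenly between VEH and ATP so there is no composition difference
#' by construction.
#'
#' @param n_per_archetype named or ordered counts for (amoeboid,
#'   intermediate, ramified).
#' @param means,sds archetype parameter matrices; defaults from
#'   [feature_archetype_params].
#' @param seed RNG seed.
#' @return data.frame with `cell_id`, `animal_id`, `group`, the eight
#'   parameter columns, and the hidden truth column `archetype`.
#' @export
generate_feature_table <- function(n_per_archetype = c(80, 80, 80),
                                   means = NULL, sds = NULL, seed = 1L) {
  pars <- feature_archetype_params()
  if (is.null(means)) means <- pars$means
  if (is.null(sds)) sds <- pars$sds
  if (any(sds <= 0)) stop("archetype SDs must be strictly positive")
  set.seed(seed)
  arch <- rep(rownames(means), times = n_per_archetype)
  feats <- draw_archetype_features(arch, means, sds)
  n <- length(arch)
  grp <- unlist(lapply(n_per_archetype, function(k)
    rep(c("VEH", "ATP"), length.out = k)))
  data.frame(cell_id = seq_len(n),
             animal_id = paste0("sim", (seq_len(n) - 1L) %% 4L + 1L),
             group = grp, feats, archetype = arch,
             stringsAsFactors = FALSE)
}

#' Generate a two-group mixture with shifted archetype proportions
#'
#' Emulates a treatment that redistributes cells across morphological
#' subpopulations without changing the parameter values within each
#' subpopulation: both groups draw archetypes multinomially, VEH with
#' `prop_veh` and ATP with `prop_atp`, from identical per-archetype feature
#' distributions.
#'
#' @param n_per_group cells per group.
#' @param prop_veh,prop_atp archetype proportions (amoeboid, intermediate,
#'   ramified); equal proportions produce a null (no-shift) design.
#' @param means,sds archetype parameter matrices.
#' @param seed RNG seed.
#' @return data.frame as in [generate_feature_table].
#' @export
generate_group_mixture <- function(n_per_group = 120,
                                   prop_veh = c(1, 1, 1) / 3,
                                   prop_atp = c(0.5, 0.3, 0.2),
                                   means = NULL, sds = NULL, seed = 1L) {
  pars <- feature_archetype_params()
  if (is.null(means)) means <- pars$means
  if (is.null(sds)) sds <- pars$sds
  set.seed(seed)
  arch_levels <- rownames(means)
  arch <- c(sample(arch_levels, n_per_group, replace = TRUE, prob = prop_veh),
            sample(arch_levels, n_per_group, replace = TRUE, prob = prop_atp))
  grp <- rep(c("VEH", "ATP"), each = n_per_group)
  feats <- draw_archetype_features(arch, means, sds)
  data.frame(cell_id = seq_along(arch),
             animal_id = paste0(grp, (seq_along(arch) - 1L) %% 4L + 1L),
             group = grp, feats, archetype = arch,
             stringsAsFactors = FALSE)
}
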