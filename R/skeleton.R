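# Skeleton extraction and branch-graph analysis.
#
# A cell mask is thinned to a one-voxel-wide curve skeleton by sequential
# removal of simple points in increasing distance-transform order (so the
# skeleton is medially centered); curve endpoints (exactly one foreground
# 26-neighbor) are preserved. Skeleton voxels are then connected under
# 26-adjacency with physical step lengths as edge weights. Because a digital
# curve can carry redundant chord adjacencies (a diagonal shortcut across two
# axis steps), the voxel graph is reduced to its minimum spanning tree before
# analysis; the number of independent cycles removed is recorded.

cell_local_mask <- function(cell, pad = 1L, fill_holes = FALSE) {
  vox <- cell$voxels
  lo <- c(min(vox[, 1]), min(vox[, 2]), min(vox[, 3])) - pad
  hi <- c(max(vox[, 1]), max(vox[, 2]), max(vox[, 3])) + pad
  d <- hi - lo + 1L
  mask <- array(FALSE, d)
  mask[cbind(vox[, 1] - lo[1] + 1L, vox[, 2] - lo[2] + 1L,
             vox[, 3] - lo[3] + 1L)] <- TRUE
  if (fill_holes) {
    # enclosed background cavities (noise dropouts inside soma or tubes)
    # corrupt the distance transform and force the skeleton around them
    bg <- array(.cc_label_3d(!mask, d, 6L), d)
    outside <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                        bg[, , 1], bg[, , d[3]]))
    outside <- outside[outside > 0L]
    mask[bg > 0L & !(bg %in% outside)] <- TRUE
  }
  list(mask = mask, offset = lo - 1L)  # absolute = local + offset
}

# 26-adjacency edges among a set of voxel coordinates (n x 3, 1-based, local)
voxel_adjacency <- function(coords, dims, spacing) {
  n <- nrow(coords)
  id <- array(0L, dims)
  id[coords] <- seq_len(n)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  # forward half-space to avoid duplicate edges
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
               (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    z2 <- coords[, 1] + offs$dz[r]
    y2 <- coords[, 2] + offs$dy[r]
    x2 <- coords[, 3] + offs$dx[r]
    ok <- z2 >= 1 & z2 <= dims[1] & y2 >= 1 & y2 <= dims[2] &
          x2 >= 1 & x2 <= dims[3]
    if (!any(ok)) next
    j <- rep(0L, n)
    j[ok] <- id[cbind(z2[ok], y2[ok], x2[ok])]
    hit <- which(j > 0L)
    if (!length(hit)) next
    from <- c(from, hit)
    to <- c(to, j[hit])
    w <- c(w, rep(sqrt(sum((c(offs$dz[r], offs$dy[r], offs$dx[r]) * spacing)^2)),
                  length(hit)))
  }
  list(from = from, to = to, weight = w)
}

new_skeleton_graph <- function(coords, edges, spacing, degenerate,
                               n_cycles = 0L) {
  structure(list(coords = coords, edges = edges, spacing = spacing,
                 degenerate = degenerate, n_cycles = as.integer(n_cycles)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d voxel(s), %d edge(s)%s\n",
              nrow(x$coords), length(x$edges$from),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Decompose a skeleton graph into critical nodes and branches.
# Critical entities are endpoints (degree-1 voxels) and junction clusters
# (26-connected clusters of degree >= 3 voxels; a thick junction maps to one
# branchpoint). Branches are maximal degree-2 paths between critical
# entities; adjacencies internal to one junction cluster are not branches.
# Junction clusters with voxels inside the cell's maximal inscribed sphere
# (sk$inside, set by skeletonize) are merged into a single hub: branches
# meeting inside the cell body all emanate from the one soma.
skeleton_branches <- function(sk) {
  n <- nrow(sk$coords)
  deg <- tabulate(c(sk$edges$from, sk$edges$to), nbins = n)
  endpoint <- deg == 1L
  junction <- deg >= 3L

  # junction clusters via union of edges between junction voxels
  cluster <- integer(n)
  if (any(junction)) {
    jid <- which(junction)
    g <- igraph::make_empty_graph(n = length(jid), directed = FALSE)
    sel <- junction[sk$edges$from] & junction[sk$edges$to]
    if (any(sel)) {
      m <- match(c(rbind(sk$edges$from[sel], sk$edges$to[sel])), jid)
      g <- igraph::add_edges(g, m)
    }
    comp <- igraph::components(g)$membership
    cluster[jid] <- comp
    if (!is.null(sk$inside)) {
      hub <- unique(cluster[jid][sk$inside[jid]])
      if (length(hub) > 1L) {
        cluster[jid][cluster[jid] %in% hub] <- hub[1]
      }
      # compact cluster ids
      u <- sort(unique(cluster[jid]))
      cluster[jid] <- match(cluster[jid], u)
    }
  }
  cond_id <- ifelse(endpoint, paste0("e", seq_len(n)),
                    ifelse(junction, paste0("j", cluster), NA_character_))

  ne <- length(sk$edges$from)
  adj <- vector("list", n)
  for (k in seq_len(ne)) {
    i <- sk$edges$from[k]; j <- sk$edges$to[k]
    adj[[i]] <- rbind(adj[[i]], c(j, k))
    adj[[j]] <- rbind(adj[[j]], c(i, k))
  }
  edge_seen <- logical(ne)
  critical <- endpoint | junction

  # physical length of a voxel path: step lengths are summed along the path
  # after resampling it every six voxels (~3 um at the default spacing).
  # Thinning leaves a +-1 voxel wobble around the medial axis, and raw
  # voxel-to-voxel step sums inflate oblique branch lengths by up to ~30%;
  # chord resampling suppresses the wobble while losing < 1% to genuine
  # curvature. The stride is in voxels, so lengths scale exactly with
  # spacing
  path_length <- function(path) {
    if (length(path) < 2L) return(0)
    pts <- sweep(sk$coords[path, , drop = FALSE], 2, sk$spacing, "*")
    idx <- unique(c(seq(1L, nrow(pts), by = 6L), nrow(pts)))
    pp <- pts[idx, , drop = FALSE]
    sum(sqrt(rowSums(diff(pp)^2)))
  }

  starts <- numeric(0); ends <- character(0); lens <- numeric(0)
  startsc <- character(0)
  paths <- list()
  for (u in which(critical)) {
    if (is.null(adj[[u]])) next
    for (r in seq_len(nrow(adj[[u]]))) {
      v <- adj[[u]][r, 1]; e <- adj[[u]][r, 2]
      if (edge_seen[e]) next
      edge_seen[e] <- TRUE
      path <- c(u, v)
      len <- sk$edges$weight[e]
      prev <- u; cur <- v
      while (!critical[cur]) {
        nb <- adj[[cur]]
        nxt_row <- nb[nb[, 1] != prev, , drop = FALSE]
        if (nrow(nxt_row) == 0L) break  # isolated chain end (degree-1 handled above)
        nxt <- nxt_row[1, 1]; e2 <- nxt_row[1, 2]
        edge_seen[e2] <- TRUE
        len <- len + sk$edges$weight[e2]
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      # skip adjacencies internal to one junction cluster, including paths
      # connecting merged hub sub-junctions through the cell body
      if (junction[u] && junction[cur] && cluster[u] == cluster[cur] &&
          (length(path) == 2L ||
           (!is.null(sk$inside) && all(sk$inside[path])))) next
      startsc <- c(startsc, cond_id[u])
      ends <- c(ends, cond_id[cur])
      lens <- c(lens, path_length(path))
      paths[[length(paths) + 1L]] <- path
    }
  }
  list(
    branches = data.frame(start = startsc, end = ends, length_um = lens,
                          stringsAsFactors = FALSE),
    paths = paths,
    endpoint = endpoint, junction = junction, cluster = cluster,
    n_endpoints = sum(endpoint),
    n_junction_clusters = if (any(junction)) max(cluster) else 0L
  )
}

# iteratively remove leaf branches shorter than prune_length (um); when
# `inside` (per-voxel logical: inside the cell's maximal inscribed sphere)
# is given, leaf branches contained entirely in that sphere are removed
# regardless of length — a process that never leaves the cell body is a
# thinning artifact of the soma interior
prune_skeleton <- function(sk, prune_length, inside = NULL) {
  if (sk$degenerate || (prune_length <= 0 && is.null(inside))) return(sk)
  repeat {
    br <- skeleton_branches(sk)
    if (nrow(br$branches) == 0L) return(sk)
    leaf <- substr(br$branches$start, 1, 1) == "e" |
            substr(br$branches$end, 1, 1) == "e"
    # an endpoint-to-endpoint path is the whole component: never pruned
    both_end <- substr(br$branches$start, 1, 1) == "e" &
                substr(br$branches$end, 1, 1) == "e"
    short <- br$branches$length_um < prune_length
    if (!is.null(inside)) {
      contained <- vapply(seq_len(nrow(br$branches)), function(i)
        all(inside[br$paths[[i]]]), logical(1))
      short <- short | contained
    }
    doomed <- which(leaf & !both_end & short)
    if (!length(doomed)) return(sk)
    drop <- unique(unlist(lapply(doomed, function(i) {
      path <- br$paths[[i]]
      # keep the junction-side terminal voxel; drop the rest of the spur
      if (substr(br$branches$start[i], 1, 1) == "e") path[-length(path)]
      else path[-1L]
    })))
    keep <- setdiff(seq_len(nrow(sk$coords)), drop)
    sk <- subset_skeleton(sk, keep)
    if (!is.null(inside)) inside <- inside[keep]
    if (sk$degenerate) return(sk)
  }
}

subset_skeleton <- function(sk, keep) {
  remap <- integer(nrow(sk$coords))
  remap[keep] <- seq_along(keep)
  coords <- sk$coords[keep, , drop = FALSE]
  sel <- sk$edges$from %in% keep & sk$edges$to %in% keep
  edges <- list(from = remap[sk$edges$from[sel]],
                to = remap[sk$edges$to[sel]],
                weight = sk$edges$weight[sel])
  out <- new_skeleton_graph(coords, edges, sk$spacing,
                            degenerate = nrow(coords) <= 1L,
                            n_cycles = sk$n_cycles)
  if (!is.null(sk$inside)) out$inside <- sk$inside[keep]
  out
}

#' Skeletonize a cell
#'
#' Topology-preserving 3D thinning of the cell mask to a one-voxel-wide curve
#' skeleton, followed by spur pruning: terminal branches shorter than
#' `prune_length` micrometres (thinning artifacts on rough surfaces) are
#' removed iteratively, as are junction-attached leaves lying entirely inside
#' the cell's maximal inscribed sphere (a genuine process leaves the cell
#' body, so such leaves are thinning residue of the soma interior). If the
#' final skeleton has at most one voxel, or lies entirely within the maximal
#' inscribed sphere — as for a compact convex cell with no processes — it is
#' flagged degenerate.
#'
#' @param cell a `cell_object` from [select_cells].
#' @param prune_length spur pruning threshold in um (default 2).
#' @return A `skeleton_graph`: voxel coordinates (absolute (z,y,x) indices),
#'   a 26-adjacency edge list reduced to a spanning tree with physical step
#'   lengths in um, the spacing, a `degenerate` flag and `n_cycles` (number
#'   of independent cycles removed by the spanning-tree reduction).
#' @export
skeletonize <- function(cell, prune_length = 2.0) {
  stopifnot(inherits(cell, "cell_object"))
  spacing <- cell$spacing
  lm <- cell_local_mask(cell, pad = 1L, fill_holes = TRUE)
  d <- dim(lm$mask)
  pri <- .edt_3d(as.logical(lm$mask), d, spacing)
  skel <- array(.thin_3d(as.logical(lm$mask), d, pri), d)
  idx <- which(skel)
  if (length(idx) <= 1L) {
    co <- arrayInd(idx, d)
    co <- sweep(co, 2, lm$offset, "+")
    colnames(co) <- c("z", "y", "x")
    return(new_skeleton_graph(co, list(from = integer(0), to = integer(0),
                                       weight = numeric(0)),
                              spacing, degenerate = TRUE))
  }
  co <- arrayInd(idx, d)
  ed <- voxel_adjacency(co, d, spacing)
  n <- nrow(co)
  ncomp <- {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, c(rbind(ed$from, ed$to)))
    igraph::components(g)$no
  }
  n_cycles <- length(ed$from) - n + ncomp
  if (n_cycles > 0L) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, c(rbind(ed$from, ed$to)))
    igraph::E(g)$weight <- ed$weight
    mt <- igraph::mst(g, weights = igraph::E(g)$weight)
    em <- igraph::as_edgelist(mt, names = FALSE)
    ed <- list(from = em[, 1], to = em[, 2], weight = igraph::E(mt)$weight)
  }
  co_abs <- sweep(co, 2, lm$offset, "+")
  colnames(co_abs) <- c("z", "y", "x")
  sk <- new_skeleton_graph(co_abs, ed, spacing, degenerate = FALSE,
                           n_cycles = n_cycles)

  # maximal inscribed sphere: center = distance-transform argmax (tie ->
  # lowest (z,y,x)), radius = max distance value
  dmax <- max(pri)
  cand <- arrayInd(which(pri == dmax), d)
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
  ctr_phys <- (cand[1, ] + lm$offset - 1) * spacing
  vox_phys <- sweep(sk$coords - 1, 2, spacing, "*")
  dist_ctr <- sqrt(rowSums(sweep(vox_phys, 2, ctr_phys, "-")^2))
  tol <- max(spacing)
  if (all(dist_ctr <= dmax + tol)) {
    # no process reaches beyond the soma: degenerate (no measurable branches)
    sk$degenerate <- TRUE
    return(sk)
  }
  sk$inside <- dist_ctr <= dmax + tol
  sk <- prune_skeleton(sk, prune_length, inside = sk$inside)
  if (!sk$degenerate && all(sk$inside)) sk$degenerate <- TRUE
  sk
}

#' Branch metrics of a skeleton
#'
#' Counts branchpoints (26-connected clusters of degree >= 3 skeleton voxels;
#' a thick junction counts once) and endpoints (degree-1 voxels), and reports
#' branch lengths as sums of inter-voxel physical step lengths along each
#' path between consecutive critical nodes. A degenerate skeleton yields all
#' zeros with the flag set.
#'
#' @param sk a `skeleton_graph`.
#' @return list with `branchpoints`, `endpoints`, `n_branches`,
#'   `avg_branch_um`, `min_branch_um`, `max_branch_um`, `branch_lengths_um`,
#'   `degenerate`.
#' @export
branch_metrics <- function(sk) {
  stopifnot(inherits(sk, "skeleton_graph"))
  if (sk$degenerate)
    return(list(branchpoints = 0L, endpoints = 0L, n_branches = 0L,
                avg_branch_um = 0, min_branch_um = 0, max_branch_um = 0,
                branch_lengths_um = numeric(0), degenerate = TRUE))
  br <- skeleton_branches(sk)
  lens <- br$branches$length_um
  list(branchpoints = as.integer(br$n_junction_clusters),
       endpoints = as.integer(br$n_endpoints),
       n_branches = nrow(br$branches),
       avg_branch_um = if (length(lens)) mean(lens) else 0,
       min_branch_um = if (length(lens)) min(lens) else 0,
       max_branch_um = if (length(lens)) max(lens) else 0,
       branch_lengths_um = lens,
       degenerate = FALSE)
}

#' Condensed-tree summary of a skeleton
#'
#' Exposes the condensed structure used for the tree identity: one node per
#' endpoint and per junction cluster, with each junction's degree equal to
#' the number of incident branches. For an acyclic skeleton the identity
#' `endpoints = 2 + sum(degree - 2)` over junction clusters holds.
#'
#' @param sk a `skeleton_graph`.
#' @return list with `n_endpoints`, `n_junction_clusters`,
#'   `junction_degrees`, `n_branches`, `acyclic`.
#' @export
skeleton_summary <- function(sk) {
  stopifnot(inherits(sk, "skeleton_graph"))
  if (sk$degenerate)
    return(list(n_endpoints = 0L, n_junction_clusters = 0L,
                junction_degrees = integer(0), n_branches = 0L,
                acyclic = TRUE))
  br <- skeleton_branches(sk)
  jd <- integer(0)
  if (br$n_junction_clusters > 0L) {
    inc <- c(br$branches$start, br$branches$end)
    inc <- inc[substr(inc, 1, 1) == "j"]
    jd <- as.integer(table(factor(inc, levels = paste0("j", seq_len(br$n_junction_clusters)))))
  }
  n_cond <- br$n_endpoints + br$n_junction_clusters
  acyclic <- sk$n_cycles == 0L && nrow(br$branches) == n_cond - 1L
  list(n_endpoints = as.integer(br$n_endpoints),
       n_junction_clusters = as.integer(br$n_junction_clusters),
       junction_degrees = jd,
       n_branches = nrow(br$branches),
       acyclic = acyclic)
}

#' Sholl analysis of a skeleton
#'
#' Counts, for each concentric sphere of radius `r = step, 2 step, ...` about
#' `center`, the skeleton edges whose two endpoints straddle the sphere (one
#' intersection per straddling edge), with all distances in physical units.
#' An edge straddles radius r when `min(d) < r <= max(d)`.
#'
#' @param sk a `skeleton_graph`.
#' @param center physical (z, y, x) coordinates in um of the sphere center
#'   (normally the soma centroid from [soma]).
#' @param step sphere spacing in um (> 0).
#' @param max_radius largest radius in um.
#' @return data.frame with `radius_um`, `intersections` (all zero for a
#'   degenerate skeleton).
#' @export
sholl <- function(sk, center, step, max_radius) {
  stopifnot(inherits(sk, "skeleton_graph"), step > 0)
  radii <- seq(step, max_radius, by = step)
  if (sk$degenerate || length(sk$edges$from) == 0L)
    return(data.frame(radius_um = radii, intersections = 0L))
  pos <- sweep(sk$coords - 1, 2, sk$spacing, "*")
  dctr <- sqrt(rowSums(sweep(pos, 2, center, "-")^2))
  d1 <- dctr[sk$edges$from]; d2 <- dctr[sk$edges$to]
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  counts <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  data.frame(radius_um = radii, intersections = counts)
}
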