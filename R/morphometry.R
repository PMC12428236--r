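#' Cell volume
#'
#' Volume of the fluorescent voxels composing the cell: voxel count times the
#' physical voxel volume.
#'
#' @param cell a `cell_object`.
#' @param spacing optional override of the cell's voxel spacing (dz, dy, dx).
#' @return Volume in cubic micrometres.
#' @export
cell_volume <- function(cell, spacing = cell$spacing) {
  stopifnot(inherits(cell, "cell_object"), cell$voxel_count >= 1L)
  cell$voxel_count * prod(spacing)
}

#' Territory volume (convex hull)
#'
#' The cell territory is the maximal spatial expansion of the cell: the
#' volume of the 3D convex hull of the cell's voxel centers in physical
#' coordinates. Only boundary voxels are passed to the hull construction
#' (interior voxels cannot be hull vertices). The hull of voxel centers
#' shrinks by about half a voxel relative to the voxel union, so for
#' compact convex cells the raw hull can be smaller than the cell volume;
#' the reported `territory_um3` is clamped from below at the cell volume
#' (the ramification index is then exactly 1) and the raw hull is returned
#' alongside. Collinear/coplanar cells are flagged degenerate.
#'
#' @param cell a `cell_object`.
#' @param spacing optional spacing override.
#' @return list with `territory_um3` (clamped at the cell volume),
#'   `hull_um3` (raw hull volume) and `degenerate_territory`.
#' @export
territory_volume <- function(cell, spacing = cell$spacing) {
  stopifnot(inherits(cell, "cell_object"))
  vol <- cell_volume(cell, spacing)
  lm <- cell_local_mask(cell, pad = 1L)
  m <- lm$mask
  d <- dim(m)
  # face-neighbor erosion: a voxel is interior if all six face neighbors are
  # foreground; only boundary voxels can be hull vertices
  shift <- function(a, dz, dy, dx) {
    out <- array(FALSE, dim(a))
    zs <- seq_len(d[1]) + dz; ys <- seq_len(d[2]) + dy; xs <- seq_len(d[3]) + dx
    okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okx <- xs >= 1 & xs <= d[3]
    out[okz, oky, okx] <- a[zs[okz], ys[oky], xs[okx]]
    out
  }
  interior <- m & shift(m, 1, 0, 0) & shift(m, -1, 0, 0) &
    shift(m, 0, 1, 0) & shift(m, 0, -1, 0) &
    shift(m, 0, 0, 1) & shift(m, 0, 0, -1)
  boundary <- m & !interior
  co <- which(boundary, arr.ind = TRUE)
  pts <- cbind(co[, 1] * spacing[1], co[, 2] * spacing[2], co[, 3] * spacing[3])
  h <- .hull3_volume(pts)
  if (h$degenerate)
    return(list(territory_um3 = vol, hull_um3 = h$volume,
                degenerate_territory = TRUE))
  list(territory_um3 = max(h$volume, vol), hull_um3 = h$volume,
       degenerate_territory = FALSE)
}

#' Ramification index
#'
#' Territory volume divided by cell volume. Values near 1 indicate compact,
#' amoeboid cells whose convex territory barely exceeds their own volume;
#' large values indicate ramified cells spanning a territory much larger
#' than their fluorescent volume.
#'
#' @param territory territory volume, um^3.
#' @param volume cell volume, um^3 (> 0).
#' @return Dimensionless ratio.
#' @export
ramification_index <- function(territory, volume) {
  if (volume <= 0) stop("cell volume must be positive")
  territory / volume
}

#' Soma centroid and volume
#'
#' The soma center is the voxel maximizing the Euclidean distance transform
#' of the cell mask (the deepest interior point; ties broken by lowest
#' (z, y, x)). The soma is the set of cell voxels whose distance-transform
#' value is at least `soma_fraction` of the maximum, restricted to the
#' connected component containing the center.
#'
#' @param cell a `cell_object`.
#' @param soma_fraction fraction of the maximal distance value in (0, 1\];
#'   default 0.5.
#' @param spacing optional spacing override.
#' @return list with `centroid` (physical (z, y, x) in um, stack origin at
#'   voxel (1,1,1) = (0,0,0)) and `soma_um3`.
#' @export
soma <- function(cell, soma_fraction = 0.5, spacing = cell$spacing) {
  stopifnot(inherits(cell, "cell_object"))
  lm <- cell_local_mask(cell, pad = 1L, fill_holes = TRUE)
  d <- dim(lm$mask)
  dt <- array(.edt_3d(as.logical(lm$mask), d, spacing), d)
  dmax <- max(dt)
  cand <- which(dt == dmax)
  co <- arrayInd(cand, d)
  ord <- order(co[, 1], co[, 2], co[, 3])
  center_local <- co[ord[1], ]
  soma_mask <- lm$mask & dt >= soma_fraction * dmax
  labs <- array(.cc_label_3d(as.logical(soma_mask), d, 26L), d)
  center_lab <- labs[matrix(center_local, 1)]
  n_soma <- sum(labs == center_lab)
  center_abs <- center_local + lm$offset
  list(centroid = (center_abs - 1) * spacing,
       soma_um3 = n_soma * prod(spacing))
}

#' Measure all selected cells
#'
#' Assembles the full morphometric record for every included cell: cell
#' volume, convex-hull territory, ramification index, branchpoint and
#' endpoint counts, average/min/max branch length, soma volume and the 3D
#' Sholl profile centered on the soma. Excluded cells appear only in the
#' audit table, never here.
#'
#' @param cells list of `cell_object`s from [select_cells].
#' @param config config list (see [default_config]); uses `prune_length`,
#'   `soma_fraction`, `sholl_step`, `sholl_max_radius`.
#' @param animal_id,group_label labels attached to every record.
#' @return list with `records` (one data.frame row per included cell, columns
#'   `cell_id, animal_id, group, cell_volume_um3, territory_um3,
#'   ramification_index, branchpoints, endpoints, avg_branch_um,
#'   min_branch_um, max_branch_um, soma_um3, degenerate_skeleton`), `sholl`
#'   (long data.frame `cell_id, radius_um, intersections`) and `skeletons`
#'   (named list of `skeleton_graph`s).
#' @export
measure_cells <- function(cells, config = default_config(), animal_id = "",
                          group_label = "") {
  inc <- Filter(function(cl) cl$included, cells)
  rows <- list(); sholls <- list(); skels <- list()
  for (cl in inc) {
    vol <- cell_volume(cl)
    terr <- territory_volume(cl)
    ri <- ramification_index(terr$territory_um3, vol)
    sk <- skeletonize(cl, prune_length = config$prune_length)
    bm <- branch_metrics(sk)
    so <- soma(cl, soma_fraction = config$soma_fraction)
    sh <- sholl(sk, so$centroid, config$sholl_step, config$sholl_max_radius)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cl$cell_id, animal_id = animal_id, group = group_label,
      cell_volume_um3 = vol, territory_um3 = terr$territory_um3,
      ramification_index = ri,
      branchpoints = bm$branchpoints, endpoints = bm$endpoints,
      avg_branch_um = bm$avg_branch_um, min_branch_um = bm$min_branch_um,
      max_branch_um = bm$max_branch_um, soma_um3 = so$soma_um3,
      degenerate_skeleton = bm$degenerate,
      stringsAsFactors = FALSE)
    sh$cell_id <- cl$cell_id
    sholls[[length(sholls) + 1L]] <- sh[, c("cell_id", "radius_um", "intersections")]
    skels[[as.character(cl$cell_id)]] <- sk
  }
  records <- if (length(rows)) do.call(rbind, rows) else data.frame()
  sholl_df <- if (length(sholls)) do.call(rbind, sholls) else data.frame()
  list(records = records, sholl = sholl_df, skeletons = skels)
}
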