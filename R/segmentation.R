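#' Otsu threshold of an intensity stack
#'
#' Computes the Otsu threshold over the full-stack histogram: the integer
#' level `t` maximizing the between-class variance of the split
#' background = \{v <= t\} / foreground = \{v > t\}. Among tied maximizers the
#' lowest level is returned, so thresholding is bit-exact and reproducible.
#' The threshold is computed per stack, never pooled across a cohort.
#'
#' @param x a [voxel_grid] or a vector of non-negative integer intensities
#'   (a flattened stack works).
#' @return The threshold level (integer-valued numeric). Foreground is
#'   strictly above the threshold.
#' @export
otsu_threshold <- function(x) {
  v <- if (inherits(x, "voxel_grid")) as.vector(x$data) else as.vector(x)
  if (any(v < 0) || any(v != round(v)))
    stop("intensities must be non-negative integers")
  lev <- sort(unique(v))
  if (length(lev) < 2L)
    stop("degenerate histogram: stack has fewer than 2 distinct intensity values")
  counts <- tabulate(v + 1L, nbins = max(v) + 1L)
  levels <- 0:max(v)
  n <- sum(counts)
  # cumulative sums are exact integers, so the class means below match a
  # direct per-threshold evaluation bit for bit
  c0 <- cumsum(counts)
  s0 <- cumsum(counts * levels)
  c1 <- n - c0
  s1 <- s0[length(s0)] - s0
  w0 <- c0 / n
  w1 <- c1 / n
  sigma_b <- ifelse(c0 > 0 & c1 > 0,
                    w0 * w1 * (s0 / c0 - s1 / c1)^2, 0)
  levels[which.max(sigma_b)]  # which.max returns the first (lowest) maximizer
}

#' Binarize a stack and label connected components
#'
#' Foreground is the set of voxels strictly above `threshold`. Connected
#' components are labeled under the configured connectivity (26 by default so
#' thin diagonal processes do not fragment); components smaller than
#' `min_object_voxels` are removed (the noise filter), and survivors are
#' relabeled densely 1..n in first-encounter order.
#'
#' @param grid a [voxel_grid].
#' @param threshold intensity level; foreground is `> threshold`.
#' @param min_object_voxels noise filter: minimum object size in voxels.
#' @param connectivity 6, 18 or 26.
#' @return A `label_map`: list with `labels` (3D integer array, 0 =
#'   background), `n_objects`, `connectivity`, `spacing`.
#' @export
binarize <- function(grid, threshold, min_object_voxels = 1L,
                     connectivity = 26L) {
  stopifnot(inherits(grid, "voxel_grid"))
  min_object_voxels <- as.integer(min_object_voxels)
  if (min_object_voxels < 1L) stop("min_object_voxels must be >= 1")
  mask <- grid$data > threshold
  label_mask(mask, grid$spacing, min_object_voxels, connectivity)
}

#' Label a binary mask directly
#'
#' Lower-level entry point of [binarize] for masks that are already binary.
#'
#' @param mask logical 3D array in (z, y, x) order.
#' @param spacing voxel spacing (dz, dy, dx) in um.
#' @param min_object_voxels minimum object size kept.
#' @param connectivity 6, 18 or 26.
#' @return A `label_map` (see [binarize]).
#' @export
label_mask <- function(mask, spacing = c(1, 1, 1), min_object_voxels = 1L,
                       connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  raw <- .cc_label_3d(as.logical(mask), dim(mask), as.integer(connectivity))
  n_raw <- attr(raw, "n")
  labels <- array(as.integer(raw), dim(mask))
  if (n_raw > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = n_raw)
    keep <- which(sizes >= min_object_voxels)
    remap <- integer(n_raw)
    remap[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
    n <- length(keep)
  } else n <- 0L
  structure(list(labels = labels, n_objects = as.integer(n),
                 connectivity = as.integer(connectivity),
                 spacing = as.numeric(spacing)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d, %d object(s), connectivity %d\n",
              d[1], d[2], d[3], x$n_objects, x$connectivity))
  invisible(x)
}

#' Extract per-object cell records from a label map
#'
#' Each labeled component becomes a cell object carrying its voxel indices,
#' voxel count and interior fraction (the fraction of voxels not lying on any
#' of the six faces of the stack), with inclusion flags initialized to
#' included / reason "none".
#'
#' @param label_map a `label_map` from [binarize] or [label_mask].
#' @return A list of `cell_object`s.
#' @export
extract_cells <- function(label_map) {
  stopifnot(inherits(label_map, "label_map"))
  d <- dim(label_map$labels)
  idx <- which(label_map$labels > 0L)
  if (length(idx) == 0L) return(list())
  lab <- label_map$labels[idx]
  co <- arrayInd(idx, d)  # columns: z, y, x (1-based)
  on_face <- co[, 1] == 1L | co[, 1] == d[1] |
             co[, 2] == 1L | co[, 2] == d[2] |
             co[, 3] == 1L | co[, 3] == d[3]
  lapply(seq_len(label_map$n_objects), function(id) {
    sel <- lab == id
    vox <- co[sel, , drop = FALSE]
    colnames(vox) <- c("z", "y", "x")
    structure(list(
      cell_id = id,
      voxels = vox,
      voxel_count = nrow(vox),
      interior_fraction = 1 - mean(on_face[sel]),
      included = TRUE,
      exclusion_reason = "none",
      grid_dim = d,
      spacing = label_map$spacing
    ), class = "cell_object")
  })
}

#' Calibrate the cell-size gate from two reference cells
#'
#' Mirrors the interactive calibration step in which the user points at the
#' largest single (non-merged) cell and the smallest complete cell: objects
#' larger than the former are presumed merged cells, objects smaller than the
#' latter are presumed debris. Identifying cells by id (or voxel count, via
#' the gate vector directly) keeps batch runs reproducible; see
#' [object_size_table] for a ranked size listing that mimics the GUI step.
#'
#' @param label_map a `label_map`.
#' @param largest_single_cell,smallest_complete_cell object ids in the map.
#' @return Named numeric `c(min_voxels, max_voxels)`.
#' @export
calibrate_size_gate <- function(label_map, largest_single_cell,
                                smallest_complete_cell) {
  stopifnot(inherits(label_map, "label_map"))
  sizes <- tabulate(label_map$labels[label_map$labels > 0L],
                    nbins = label_map$n_objects)
  for (id in c(largest_single_cell, smallest_complete_cell))
    if (id < 1L || id > label_map$n_objects)
      stop("cell id not present in label map: ", id)
  gate <- c(min_voxels = sizes[smallest_complete_cell],
            max_voxels = sizes[largest_single_cell])
  if (gate["min_voxels"] > gate["max_voxels"])
    stop("inconsistent calibration: chosen smallest cell is larger than chosen largest cell")
  gate
}

#' Ranked object-size table
#'
#' Helper mimicking the interactive size display: object ids and voxel counts
#' sorted by decreasing size.
#'
#' @param label_map a `label_map`.
#' @return data.frame with `cell_id`, `voxel_count`.
#' @export
object_size_table <- function(label_map) {
  sizes <- tabulate(label_map$labels[label_map$labels > 0L],
                    nbins = label_map$n_objects)
  out <- data.frame(cell_id = seq_len(label_map$n_objects), voxel_count = sizes)
  out[order(-out$voxel_count), , drop = FALSE]
}

apply_size_gate <- function(cells, gate) {
  lapply(cells, function(cl) {
    if (cl$exclusion_reason != "none") return(cl)
    if (cl$voxel_count < gate[["min_voxels"]]) {
      cl$included <- FALSE; cl$exclusion_reason <- "too_small"
    } else if (cl$voxel_count > gate[["max_voxels"]]) {
      cl$included <- FALSE; cl$exclusion_reason <- "too_large"
    }
    cl
  })
}

#' Mark incomplete (border-clipped) cells
#'
#' A cell is complete when at least `interior_min` of its voxels lie away
#' from the six faces of the stack (default 0.8, i.e. at least 80% of the
#' soma-plus-process voxels inside the imaged volume; soma and processes are
#' weighted equally, every voxel counting once). Cells already excluded for
#' another reason are left untouched, so the filter composes idempotently
#' with the size gate.
#'
#' @param cells list of `cell_object`s.
#' @param interior_min minimum interior fraction in \[0, 1\].
#' @return The cell list with exclusion flags updated; ordering preserved.
#' @export
filter_incomplete <- function(cells, interior_min = 0.8) {
  lapply(cells, function(cl) {
    if (cl$exclusion_reason != "none") return(cl)
    if (cl$interior_fraction < interior_min) {
      cl$included <- FALSE; cl$exclusion_reason <- "incomplete"
    }
    cl
  })
}

#' Select cells for measurement
#'
#' Applies the size gate, then the border-completeness filter, then manual
#' overrides (which always win). All cells are returned with their flags so
#' the exclusion audit trail stays reportable; excluded cells simply carry
#' `included = FALSE` and a reason.
#'
#' @param label_map a `label_map`.
#' @param gate optional `c(min_voxels, max_voxels)` from
#'   [calibrate_size_gate] (or chosen directly).
#' @param interior_min border filter threshold; see [filter_incomplete].
#' @param manual_overrides optional list of `list(cell_id =, action =)` with
#'   action "include" or "exclude".
#' @return List of `cell_object`s, one per labeled object.
#' @export
select_cells <- function(label_map, gate = NULL, interior_min = 0.8,
                         manual_overrides = NULL) {
  cells <- extract_cells(label_map)
  if (!is.null(gate)) cells <- apply_size_gate(cells, gate)
  cells <- filter_incomplete(cells, interior_min)
  if (!is.null(manual_overrides)) {
    ids <- vapply(cells, function(cl) cl$cell_id, integer(1))
    for (ov in manual_overrides) {
      pos <- match(ov$cell_id, ids)
      if (is.na(pos)) stop("manual override references unknown cell id: ", ov$cell_id)
      if (identical(ov$action, "include")) {
        cells[[pos]]$included <- TRUE
        cells[[pos]]$exclusion_reason <- "none"
      } else if (identical(ov$action, "exclude")) {
        cells[[pos]]$included <- FALSE
        cells[[pos]]$exclusion_reason <- "manual"
      } else stop("override action must be \"include\" or \"exclude\"")
    }
  }
  cells
}

#' Per-object audit table
#'
#' @param cells list of `cell_object`s.
#' @return data.frame with columns `cell_id`, `voxel_count`,
#'   `interior_fraction`, `included`, `exclusion_reason`.
#' @export
audit_table <- function(cells) {
  data.frame(
    cell_id = vapply(cells, function(x) x$cell_id, integer(1)),
    voxel_count = vapply(cells, function(x) x$voxel_count, integer(1)),
    interior_fraction = vapply(cells, function(x) x$interior_fraction, numeric(1)),
    included = vapply(cells, function(x) x$included, logical(1)),
    exclusion_reason = vapply(cells, function(x) x$exclusion_reason, character(1))
  )
}

#' One-call segmentation of a stack
#'
#' Otsu threshold, noise-filtered labeling and cell selection in one step.
#'
#' @param grid a [voxel_grid].
#' @param config a config list; see [default_config].
#' @param gate optional size gate `c(min_voxels, max_voxels)`.
#' @param manual_overrides see [select_cells].
#' @return list with `threshold`, `label_map`, `cells`, `audit`.
#' @export
segment_stack <- function(grid, config = default_config(), gate = NULL,
                          manual_overrides = NULL) {
  thr <- otsu_threshold(grid)
  lm <- binarize(grid, thr, config$min_object_voxels, config$connectivity)
  cells <- select_cells(lm, gate = gate, interior_min = config$interior_min,
                        manual_overrides = manual_overrides)
  list(threshold = thr, label_map = lm, cells = cells,
       audit = audit_table(cells))
}
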