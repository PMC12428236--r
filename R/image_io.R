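#' Construct a voxel grid
#'
#' A `voxel_grid` couples a 3D intensity array with its physical voxel
#' spacing. The axis order is fixed as (z, y, x) everywhere in the package:
#' the first array dimension indexes optical sections, the second image rows,
#' the third image columns. Spacing is supplied by the user (typically from
#' the acquisition protocol, e.g. 0.5 um axial steps and 0.172 um pixel
#' pitch) rather than parsed from TIFF tags, which keeps runs bit-exactly
#' reproducible across acquisition software.
#'
#' @param data numeric or integer 3D array in (z, y, x) order.
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in micrometres; all
#'   entries must be strictly positive and finite.
#' @param source_id free-text provenance string stored with the grid.
#' @return An object of class `voxel_grid`: a list with elements `data`,
#'   `spacing` and `source_id`.
#' @examples
#' g <- voxel_grid(array(0L, c(4, 8, 8)), spacing = c(0.5, 0.172, 0.172))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing, source_id = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values (dz, dy, dx)")
  structure(list(data = data, spacing = spacing,
                 source_id = as.character(source_id)[1]),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %.4g x %.4g x %.4g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read a multi-page TIFF z-stack
#'
#' Reads a single-channel 8- or 16-bit multi-page TIFF; page order maps to the
#' z axis. Intensities are kept as raw integer counts, never rescaled, so the
#' Otsu threshold operates on the native histogram.
#'
#' @param path path to the TIFF file.
#' @param spacing physical voxel spacing `(dz, dy, dx)` in micrometres.
#' @param source_id provenance string; defaults to the file path.
#' @return A [voxel_grid].
#' @export
read_stack <- function(path, spacing, source_id = path) {
  if (!file.exists(path)) stop("cannot read stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nd <- length(dim(pages[[1]]))
  if (nd == 3L)
    stop(sprintf("expected a single-channel stack but page 1 has %d channels",
                 dim(pages[[1]])[3]))
  if (nd != 2L) stop("unsupported TIFF page layout")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0L, c(length(pages), ny, nx))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (!all(dim(pg) == c(ny, nx))) stop("TIFF pages have inconsistent sizes")
    arr[k, , ] <- as.integer(pg)
  }
  voxel_grid(arr, spacing, source_id)
}

#' Write a voxel grid as a multi-page TIFF
#'
#' Integer-valued grids round-trip losslessly through [read_stack]. Values
#' must fit the chosen bit depth.
#'
#' @param grid a [voxel_grid] with non-negative integer-valued data.
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, bits = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$data
  if (any(v < 0) || any(v != round(v)))
    stop("write_stack requires non-negative integer-valued data")
  vmax <- max(v)
  if (is.null(bits)) bits <- if (vmax > 255) 16L else 8L
  top <- 2^bits - 1
  if (vmax > top) stop(sprintf("values exceed %d-bit range", bits))
  pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , , drop = TRUE] / top)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write stack to ", path)
  invisible(path)
}

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline in one list, overridable from a
#' YAML/JSON file via [read_config]. Units are micrometres unless noted.
#'
#' @return A named list of parameters:
#' \describe{
#'   \item{spacing}{voxel spacing (dz, dy, dx), um.}
#'   \item{connectivity}{voxel connectivity for component labeling (6/18/26).}
#'   \item{min_object_voxels}{noise filter: smallest object kept, voxels.}
#'   \item{interior_min}{minimum fraction of a cell's voxels away from the
#'     stack's six faces for the cell to count as complete (border filter).}
#'   \item{prune_length}{skeleton spur branches shorter than this are removed.}
#'   \item{soma_fraction}{soma = voxels whose distance-transform value is at
#'     least this fraction of the cell maximum.}
#'   \item{sholl_step, sholl_max_radius}{Sholl sphere spacing and cap, um.}
#'   \item{k, n_init}{K-means cluster count and random restarts.}
#'   \item{umap_n_neighbors, umap_min_dist, umap_n_epochs}{UMAP
#'     hyperparameters.}
#'   \item{cluster_space}{"umap" (default) or "pca": space K-means runs in.}
#'   \item{seed}{seed used for UMAP/K-means.}
#' }
#' @export
default_config <- function() {
  list(
    spacing = c(0.5, 0.172, 0.172),
    connectivity = 26L,
    min_object_voxels = 30L,
    interior_min = 0.8,
    prune_length = 2.0,
    soma_fraction = 0.5,
    sholl_step = 2.0,
    sholl_max_radius = 50.0,
    k = 3L,
    n_init = 10L,
    umap_n_neighbors = 15L,
    umap_min_dist = 0.1,
    umap_n_epochs = 200L,
    cluster_space = "umap",
    seed = 1L
  )
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON) file and merges it over [default_config]; unknown
#' keys are kept so module-specific extensions pass through.
#'
#' @param path YAML or JSON config file.
#' @return A config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$spacing <- as.numeric(cfg$spacing)
  cfg
}
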