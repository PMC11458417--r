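#' 4D voxelwise timeseries volume
#'
#' @param data 4D numeric array (nx, ny, nz, T), T >= 1. Values are the
#'   cleaned signal in arbitrary units (e.g., percent signal change).
#' @param geometry a \code{grid_geometry} matching the first three dims.
#' @return An object of class \code{timeseries4d}.
#' @export
timeseries4d <- function(data, geometry) {
  d <- dim(data)
  stopifnot(length(d) == 4, identical(d[1:3], as.integer(geometry$shape)))
  structure(list(data = data, geometry = geometry, n_timepoints = d[4]),
            class = "timeseries4d")
}

#' @export
print.timeseries4d <- function(x, ...) {
  cat(sprintf("timeseries4d: %d x %d x %d voxels, %d timepoints\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$n_timepoints))
  invisible(x)
}

check_factor <- function(factor) {
  factor <- rep_len(as.integer(factor), 3)
  if (any(is.na(factor)) || any(factor < 1)) {
    stop("downsampling factor must be an integer >= 1 per axis")
  }
  factor
}

# map each source voxel index (0-based) to its target cell (0-based)
down_geometry <- function(geometry, factor) {
  new_shape <- as.integer(ceiling(geometry$shape / factor))
  # target index -> centre of its source block, in source-index units
  scale <- rbind(cbind(diag(as.numeric(factor)), (factor - 1) / 2), c(0, 0, 0, 1))
  grid_geometry(new_shape, geometry$voxel_size * factor,
                geometry$affine %*% scale)
}

# 0-based target cell id (single integer) for every source voxel, plus target dims
down_cell_index <- function(shape, factor) {
  ns <- as.integer(ceiling(shape / factor))
  i <- rep.int(seq_len(shape[1]) - 1L, times = shape[2] * shape[3]) %/% factor[1]
  j <- rep.int(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3]) %/% factor[2]
  k <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2]) %/% factor[3]
  list(cell = 1L + i + ns[1] * (j + ns[2] * k), shape = ns)
}

#' Downsample a mask to a coarser grid
#'
#' Parcellation is typically run at a coarser resolution than the acquired
#' data (e.g., 2 mm data analysed at 6 mm) to keep the voxel-pair matrices
#' tractable. Each target cell aggregates a \code{factor[1] x factor[2] x
#' factor[3]} block of source voxels; partial blocks at the grid edge are
#' allowed and judged on their in-grid voxels only.
#'
#' @param mask a \code{volume_mask}.
#' @param factor integer >= 1 per axis (recycled from length 1).
#' @param min_occupancy minimum fraction of a target cell's in-grid source
#'   voxels that must be members for the cell to be a member. The default 0.5
#'   keeps cells that are at least half covered; use a small positive value
#'   (e.g., \code{1e-9}) for "any occupancy".
#' @return A \code{volume_mask} on the downsampled grid.
#' @export
downsample_mask <- function(mask, factor, min_occupancy = 0.5) {
  factor <- check_factor(factor)
  if (all(factor == 1L)) return(mask)
  geom <- down_geometry(mask$geometry, factor)
  ci <- down_cell_index(mask$geometry$shape, factor)
  hits <- tabulate(ci$cell[as.vector(mask$array)], nbins = prod(ci$shape))
  tot <- tabulate(ci$cell, nbins = prod(ci$shape))
  arr <- array(hits / tot >= min_occupancy, dim = ci$shape)
  volume_mask(arr, geom, role = mask$role, name = mask$name)
}

#' Downsample a 4D timeseries volume
#'
#' Each target cell's series is the plain mean of its in-grid source voxels'
#' series at every timepoint.
#'
#' @param vol a \code{timeseries4d}.
#' @inheritParams downsample_mask
#' @return A \code{timeseries4d} on the downsampled grid.
#' @export
downsample_timeseries <- function(vol, factor) {
  factor <- check_factor(factor)
  if (all(factor == 1L)) return(vol)
  geom <- down_geometry(vol$geometry, factor)
  ci <- down_cell_index(vol$geometry$shape, factor)
  nt <- vol$n_timepoints
  src <- matrix(vol$data, ncol = nt)           # voxels x T, column-major
  sums <- rowsum(src, group = ci$cell)         # cells present, sorted ids
  cnt <- tabulate(ci$cell, nbins = prod(ci$shape))
  out <- matrix(0, nrow = prod(ci$shape), ncol = nt)
  out[as.integer(rownames(sums)), ] <- sums
  out <- out / cnt
  timeseries4d(array(out, c(ci$shape, nt)), geom)
}

#' Extract a voxels-by-timepoints matrix for a mask
#'
#' Rows follow the canonical voxel ordering (see \code{\link{mask_members}}),
#' so matrices extracted from different participants with the same mask are
#' row-aligned.
#'
#' @param vol a \code{timeseries4d}.
#' @param mask a \code{volume_mask} on the same grid.
#' @param participant_id identifier stored with the matrix.
#' @return A numeric matrix of class \code{ts_matrix} (|mask| x T) with
#'   attributes \code{voxel_order} (0-based i,j,k), \code{mask_name},
#'   \code{participant_id} and \code{geometry}.
#' @export
extract_timeseries <- function(vol, mask, participant_id = "p") {
  if (!same_geometry(vol$geometry, mask$geometry)) {
    stop("grid mismatch between volume and mask")
  }
  lin <- mask_linear_index(mask)
  flat <- matrix(vol$data, ncol = vol$n_timepoints)
  m <- flat[lin, , drop = FALSE]
  ts_matrix(m, mask_members(mask), mask$name, participant_id, vol$geometry)
}

ts_matrix <- function(values, voxel_order, mask_name, participant_id, geometry) {
  stopifnot(nrow(values) == nrow(voxel_order))
  structure(values,
            voxel_order = voxel_order, mask_name = mask_name,
            participant_id = participant_id, geometry = geometry,
            class = c("ts_matrix", "matrix", "array"))
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("ts_matrix: %d voxels x %d timepoints (mask '%s', participant '%s')\n",
              nrow(x), ncol(x), attr(x, "mask_name"), attr(x, "participant_id")))
  invisible(x)
}

#' Temporal signal-to-noise ratio map
#'
#' tSNR is the voxelwise ratio of the mean signal to its standard deviation
#' (sample sd, n-1 denominator) across the scan. Low-tSNR voxels carry little
#' reliable connectivity information and are candidates for exclusion from
#' the masks.
#'
#' Degenerate voxels are reported with sentinels: zero sd with nonzero mean
#' gives \code{Inf}; zero sd with zero mean gives \code{NaN}. Both are listed
#' in the \code{flagged} attribute (0-based i,j,k).
#'
#' @param vol a \code{timeseries4d} with at least 2 timepoints.
#' @return A 3D numeric array of tSNR values with attribute \code{flagged}.
#' @export
compute_tsnr <- function(vol) {
  stopifnot(vol$n_timepoints >= 2)
  flat <- matrix(vol$data, ncol = vol$n_timepoints)
  mu <- rowMeans(flat)
  sd_ <- sqrt(rowSums((flat - mu)^2) / (vol$n_timepoints - 1))
  tsnr <- mu / sd_   # 0/0 -> NaN, x/0 -> +-Inf
  arr <- array(tsnr, vol$geometry$shape)
  bad <- which(!is.finite(arr), arr.ind = TRUE) - 1L
  attr(arr, "flagged") <- unname(bad)
  arr
}

#' High temporal-SD voxels (vessel candidates)
#'
#' Voxels dominated by large blood vessels show conspicuously high temporal
#' standard deviation; removing them from both the ROI and context masks
#' before parcellation is recommended. This returns the voxels whose temporal SD strictly
#' exceeds the given percentile of SD values (within \code{within}, when
#' supplied, else over the whole grid). With all-equal SDs the strict
#' inequality yields an empty set and an error is raised (an empty mask is
#' not representable); callers should treat that as "nothing to remove".
#'
#' @param vol a \code{timeseries4d}.
#' @param percentile percentile in (0, 100) of the SD distribution.
#' @param within optional \code{volume_mask} restricting both the percentile
#'   computation and the candidates (e.g., an in-brain mask).
#' @return A \code{volume_mask} (role context, name "high_sd") of the voxels
#'   above the cutoff, or \code{NULL} if none exceed it.
#' @export
high_sd_voxel_mask <- function(vol, percentile = 99, within = NULL) {
  stopifnot(percentile > 0, percentile < 100)
  flat <- matrix(vol$data, ncol = vol$n_timepoints)
  mu <- rowMeans(flat)
  sd_ <- sqrt(rowSums((flat - mu)^2) / (vol$n_timepoints - 1))
  sel <- if (is.null(within)) rep(TRUE, length(sd_)) else as.vector(within$array)
  cutoff <- stats::quantile(sd_[sel], percentile / 100, names = FALSE)
  keep <- sel & sd_ > cutoff
  if (!any(keep)) return(NULL)
  volume_mask(array(keep, vol$geometry$shape), vol$geometry,
              role = "context", name = "high_sd")
}

#' Write / read the 1D timeseries text dialect
#'
#' One voxel per row: three 0-based integer indices \code{i j k} followed by
#' the timepoints, whitespace-delimited. Header lines prefixed \code{#} carry
#' the grid geometry, mask name, participant id and the voxel ordering.
#' Values are written with 17 significant digits, so a write/read round trip
#' is bit-exact for doubles.
#'
#' @param ts a \code{ts_matrix}.
#' @param path output path.
#' @return \code{write_ts1d}: the path, invisibly. \code{read_ts1d}: a
#'   \code{ts_matrix}.
#' @export
write_ts1d <- function(ts, path) {
  g <- attr(ts, "geometry")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# splitparc 1D timeseries v1",
    sprintf("# participant: %s", attr(ts, "participant_id")),
    sprintf("# mask: %s", attr(ts, "mask_name")),
    sprintf("# shape: %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
    sprintf("# voxel_size: %.17g %.17g %.17g",
            g$voxel_size[1], g$voxel_size[2], g$voxel_size[3]),
    sprintf("# affine: %s", paste(sprintf("%.17g", t(g$affine)), collapse = " ")),
    sprintf("# n_timepoints: %d", ncol(ts)),
    "# columns: i j k t1..tT (0-based indices, row-major i,j,k order)"
  ), con)
  vo <- attr(ts, "voxel_order")
  body <- paste(vo[, 1], vo[, 2], vo[, 3],
                apply(matrix(sprintf("%.17g", ts), nrow = nrow(ts)), 1,
                      paste, collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_ts1d
#' @export
read_ts1d <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE)[1])
  shape <- as.integer(strsplit(get("shape"), " +")[[1]])
  vs <- as.numeric(strsplit(get("voxel_size"), " +")[[1]])
  aff <- matrix(as.numeric(strsplit(get("affine"), " +")[[1]]), 4, 4, byrow = TRUE)
  geom <- grid_geometry(shape, vs, aff)
  body <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"), as.numeric))
  ts_matrix(m[, -(1:3), drop = FALSE],
            voxel_order = matrix(as.integer(m[, 1:3]), ncol = 3),
            mask_name = get("mask"), participant_id = get("participant"),
            geometry = geom)
}
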