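#' Fill unlabeled brain voxels by nearest-neighbour interpolation
#'
#' Every in-brain voxel left unlabeled by the winner-take-all step receives
#' the label of its nearest labeled voxel, with distance measured in physical
#' mm through the grid affine (so anisotropic voxels are handled correctly).
#' Equidistant candidates are resolved by majority label, then by the lowest
#' label. This step is meant to fill small patches: fills farther than
#' \code{warn_distance} mm are counted and flagged with a warning, since
#' large unlabeled regions signal unstable connectivity rather than gaps.
#'
#' @param labelmap a \code{network_labels} whose \code{voxel_order} covers the
#'   in-brain voxels (canonical order of \code{brain_mask}).
#' @param brain_mask the in-brain \code{volume_mask} at the original
#'   resolution.
#' @param legend optional data frame describing each label's provenance
#'   (carried into the result).
#' @param warn_distance radius in mm beyond which fills are flagged
#'   (default: twice the largest voxel edge).
#' @return An object of class \code{parcellation}: list with \code{labels}
#'   (every in-brain voxel > 0), \code{geometry}, \code{voxel_order},
#'   \code{legend}, and \code{fill} (indices filled, their distances, count
#'   beyond \code{warn_distance}).
#' @export
fill_unlabeled <- function(labelmap, brain_mask, legend = NULL,
                           warn_distance = NULL) {
  lab <- labelmap$labels
  n <- mask_size(brain_mask)
  stopifnot(length(lab) == n)
  if (all(lab == 0)) stop("no labeled voxels to interpolate from")
  geom <- brain_mask$geometry
  if (is.null(warn_distance)) warn_distance <- 2 * max(geom$voxel_size)
  ijk <- mask_members(brain_mask)
  xyz <- voxel_to_world(geom, ijk)
  unl <- which(lab == 0)
  filled <- lab
  dists <- numeric(0)
  if (length(unl) > 0) {
    li <- which(lab > 0)
    src <- xyz[li, , drop = FALSE]
    src_lab <- lab[li]
    tol <- 1e-9
    # chunked distance computation keeps memory bounded
    step <- max(1L, floor(2e7 / length(li)))
    for (start in seq(1, length(unl), by = step)) {
      idx <- unl[start:min(start + step - 1, length(unl))]
      tgt <- xyz[idx, , drop = FALSE]
      d2 <- outer(rowSums(tgt^2), rep(1, nrow(src))) +
        outer(rep(1, nrow(tgt)), rowSums(src^2)) - 2 * tgt %*% t(src)
      d2[d2 < 0] <- 0
      dmin <- apply(d2, 1, min)
      for (r in seq_along(idx)) {
        cand <- src_lab[d2[r, ] <= dmin[r] + tol]
        tab <- table(cand)
        best <- as.integer(names(tab)[tab == max(tab)])
        filled[idx[r]] <- min(best)       # majority, then lowest label
      }
      dists <- c(dists, sqrt(dmin))
    }
  }
  far <- sum(dists > warn_distance)
  if (far > 0) {
    warning(sprintf("%d voxels filled from farther than %.1f mm; nearest-neighbour filling is meant for small patches",
                    far, warn_distance))
  }
  if (is.null(legend)) legend <- labelmap$legend
  structure(list(labels = filled, geometry = geom, voxel_order = ijk,
                 legend = legend,
                 fill = list(filled = unl, distances = dists,
                             n_beyond_warn = far,
                             warn_distance = warn_distance)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d in-brain voxels, %d networks, %d filled by nearest neighbour\n",
              length(x$labels), length(unique(x$labels)),
              length(x$fill$filled)))
  invisible(x)
}

#' Write the final parcellation volume
#'
#' Renders the labels as an integer NIfTI volume at the original resolution
#' (0 outside the brain), with a tab-separated legend sidecar
#' (\code{<path>_legend.tsv}) and a JSON run-metadata sidecar
#' (\code{<path>_meta.json}) when metadata is supplied.
#'
#' @param parc a \code{parcellation}.
#' @param path output .nii or .nii.gz path.
#' @param metadata optional named list (thresholds, seeds, criteria...)
#'   serialised to JSON for provenance.
#' @return the path, invisibly.
#' @export
write_parcellation <- function(parc, path, metadata = NULL) {
  arr <- array(0L, parc$geometry$shape)
  d <- parc$geometry$shape
  lin <- parc$voxel_order[, 1] + 1L +
    d[1] * (parc$voxel_order[, 2] + d[2] * parc$voxel_order[, 3])
  arr[lin] <- parc$labels
  write_nifti_array(arr, parc$geometry, path, datatype = "int16")
  base <- sub("\\.nii(\\.gz)?$", "", path)
  legend <- parc$legend
  if (is.null(legend)) {
    legend <- data.frame(label = sort(unique(parc$labels[parc$labels > 0])))
  }
  utils::write.table(legend, paste0(base, "_legend.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(base, "_meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
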