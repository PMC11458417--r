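#' Voxel grid geometry
#'
#' Describes the sampling grid of a volume: the number of voxels along each
#' axis, the physical voxel size in mm, and the affine transform mapping
#' 0-based voxel indices \code{(i, j, k)} to world coordinates in mm.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3, mm per axis (all > 0).
#'   Recycled from length 1.
#' @param affine 4x4 numeric matrix mapping homogeneous 0-based voxel indices
#'   to mm. Defaults to \code{diag(voxel_size)} with a zero origin. Must be
#'   invertible.
#' @return An object of class \code{grid_geometry}.
#' @export
grid_geometry <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  stopifnot(all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unname(as.matrix(affine))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be invertible")
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

#' World coordinates of voxel indices
#'
#' @param geometry a \code{grid_geometry}.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(geometry, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz <- cbind(ijk, 1) %*% t(geometry$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Binary volume mask
#'
#' A set of voxels within a grid, used either as a region-of-interest (ROI)
#' mask -- the voxels to be parcellated -- or as a context mask -- the voxels
#' against which ROI connectivity patterns are computed (typically the whole
#' brain).
#'
#' @param members a logical 3D array matching \code{geometry$shape}, or an
#'   n x 3 matrix of 0-based \code{(i, j, k)} voxel indices.
#' @param geometry a \code{grid_geometry}.
#' @param role \code{"roi"} or \code{"context"}.
#' @param name identifier used in file headers and legends.
#' @return An object of class \code{volume_mask} with fields \code{array}
#'   (logical 3D), \code{geometry}, \code{role}, \code{name}.
#' @export
volume_mask <- function(members, geometry, role = c("roi", "context"),
                        name = "mask") {
  role <- match.arg(role)
  if (is.array(members) && length(dim(members)) == 3) {
    stopifnot(identical(dim(members), as.integer(geometry$shape)))
    arr <- array(as.logical(members), dim = geometry$shape)
    arr[is.na(arr)] <- FALSE
  } else {
    ijk <- matrix(as.integer(members), ncol = 3)
    if (nrow(ijk) == 0) stop("mask must be non-empty")
    if (any(ijk < 0) || any(ijk >= matrix(geometry$shape, nrow(ijk), 3, byrow = TRUE))) {
      stop("mask members outside the grid")
    }
    arr <- array(FALSE, dim = geometry$shape)
    arr[ijk + 1L] <- TRUE
  }
  if (!any(arr)) stop("mask must be non-empty")
  structure(list(array = arr, geometry = geometry, role = role, name = name),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("volume_mask '%s' (%s): %d voxels on a %d x %d x %d grid\n",
              x$name, x$role, mask_size(x),
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3]))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a \code{volume_mask}.
#' @return integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$array)

#' Mask member voxels in canonical order
#'
#' The canonical voxel ordering used throughout the package is row-major over
#' \code{(i, j, k)}: sorted by i, then j, then k ascending, so k varies
#' fastest. Every extracted timeseries matrix and exported text file uses this
#' order, which makes matrices from different participants alignable.
#'
#' @param mask a \code{volume_mask}.
#' @return n x 3 integer matrix of 0-based \code{(i, j, k)} indices.
#' @export
mask_members <- function(mask) {
  w <- which(mask$array, arr.ind = TRUE) - 1L
  w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
  colnames(w) <- c("i", "j", "k")
  unname(w)
}

# linear (1-based, R column-major) indices of members in canonical order
mask_linear_index <- function(mask) {
  ijk <- mask_members(mask)
  d <- mask$geometry$shape
  as.integer(ijk[, 1] + 1L + d[1] * (ijk[, 2] + d[2] * ijk[, 3]))
}

#' Read a NIfTI volume as a 4D timeseries
#'
#' @param path path to a .nii or .nii.gz file (3D or 4D).
#' @return A \code{timeseries4d} (3D inputs become single-timepoint volumes).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 3) {
    arr <- array(arr, c(d, 1L))
    d <- dim(arr)
  }
  stopifnot(length(d) == 4)
  pix <- attr(img, "pixdim")
  if (is.null(pix) || length(pix) < 3 || any(pix[1:3] <= 0)) pix <- c(1, 1, 1)
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  if (is.null(aff) || !is.matrix(aff) || abs(det(aff)) < .Machine$double.eps) {
    aff <- diag(c(pix[1:3], 1))
  } else {
    attributes(aff) <- list(dim = dim(aff))
    # voxel size from the affine column norms; the pixdim header field is not
    # reliably preserved alongside an explicit sform
    pix <- sqrt(colSums(aff[1:3, 1:3]^2))
  }
  geom <- grid_geometry(d[1:3], pix[1:3], aff)
  timeseries4d(arr, geom)
}

#' Read a NIfTI mask
#'
#' Nonzero voxels become members.
#'
#' @inheritParams read_volume
#' @param role,name passed to \code{\link{volume_mask}}.
#' @return A \code{volume_mask}.
#' @export
read_mask <- function(path, role = c("roi", "context"), name = NULL) {
  role <- match.arg(role)
  vol <- read_volume(path)
  if (is.null(name)) name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume_mask(vol$data[, , , 1] != 0, vol$geometry, role = role, name = name)
}

# shared NIfTI writer: 3D/4D array + geometry
write_nifti_array <- function(arr, geometry, path, datatype = "auto") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  # sform only: RNifti's qform replacement re-derives quaternions and would
  # clobber the exact affine we want preserved verbatim
  img <- RNifti::`sform<-`(img, value = structure(geometry$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask as NIfTI
#' @param mask a \code{volume_mask}.
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_nifti_array(array(as.integer(mask$array), mask$geometry$shape),
                    mask$geometry, path, datatype = "int16")
}

#' Set operations on masks
#'
#' \code{mask_difference} removes the second mask's voxels from the first
#' (used, e.g., to subtract high-variance vessel voxels from an ROI or to
#' exclude the ROI from the context).
#'
#' @param a,b \code{volume_mask}s on the same grid.
#' @return A \code{volume_mask} with \code{a}'s role and name.
#' @export
mask_difference <- function(a, b) {
  stopifnot(same_geometry(a$geometry, b$geometry))
  volume_mask(a$array & !b$array, a$geometry, role = a$role, name = a$name)
}
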