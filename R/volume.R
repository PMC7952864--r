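#' Scalar volume: a 3-D grid with a voxel-to-mm affine
#'
#' The common currency for tract density maps, DTI parameter maps, fMRI
#' Z-maps and binary masks. The affine maps 0-based voxel indices
#' (i, j, k, 1) to world (mm) coordinates, following the NIfTI
#' convention; world space is RAS (x grows to the right, y anteriorly,
#' z superiorly), so the left hemisphere lies at negative x.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-mm matrix (last row 0 0 0 1).
#' @return An object of class `scalar_volume`: the array with an
#'   `affine` attribute.
#' @export
scalar_volume <- function(data, affine) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3-D array.")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) abort("`affine` must be 4x4.")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    abort("`affine` must be invertible.")
  }
  structure(data, affine = affine, class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<scalar_volume> %d x %d x %d voxels, range [%g, %g]\n",
    d[1], d[2], d[3], min(x, na.rm = TRUE), max(x, na.rm = TRUE)
  ))
  invisible(x)
}

vol_affine <- function(vol) attr(vol, "affine")

#' RAS affine for a grid centered on the world origin
#'
#' Isotropic voxels, axes aligned with RAS world axes, and the grid
#' center placed at (0, 0, 0) mm so that hemispheres split at x = 0.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @return 4x4 affine matrix.
#' @export
ras_affine <- function(grid_shape, voxel_size_mm) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1), voxel_size_mm > 0)
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -(grid_shape - 1) / 2 * voxel_size_mm
  aff
}

#' Convert voxel indices to world (mm) coordinates
#'
#' @param ijk n x 3 matrix of 1-based voxel indices (R array indexing).
#' @param affine 4x4 voxel-to-mm affine over 0-based indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz <- cbind(ijk - 1, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' World (mm) coordinates of every voxel center
#'
#' Rows are ordered like `which(...)` on the underlying array
#' (fastest-varying first axis).
#'
#' @param vol a `scalar_volume` (or its dim + affine).
#' @return (prod(dim)) x 3 matrix of mm coordinates.
#' @export
voxel_grid_mm <- function(vol) {
  d <- dim(vol)
  ijk <- arrayInd(seq_len(prod(d)), d)
  voxel_to_world(ijk, vol_affine(vol))
}

same_grid <- function(a, b) {
  identical(dim(a), dim(b)) &&
    max(abs(vol_affine(a) - vol_affine(b))) < 1e-6
}

#' Read a NIfTI file as a scalar_volume
#' @param path file path (.nii or .nii.gz).
#' @return a `scalar_volume`.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(im, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  scalar_volume(as.array(im), aff)
}

#' Write a scalar_volume to NIfTI
#' @param vol a `scalar_volume`.
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type, e.g. "double" or "uint8".
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  aff <- vol_affine(vol)
  voxdim <- sqrt(colSums(aff[1:3, 1:3]^2))
  arr <- unclass(vol)
  attr(arr, "affine") <- NULL
  im <- RNifti::asNifti(arr,
    reference = list(pixdim = c(-1, voxdim, rep(1, 4)))
  )
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}
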