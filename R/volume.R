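#' Scalar volume on a regular voxel grid
#'
#' A `scalar_volume` holds a 3-D scalar field (fractional anisotropy,
#' compartment fractions, pressure, concentration, ...) together with its
#' grid metadata: a 4x4 voxel-to-world affine, the voxel size in mm, and a
#' per-voxel brain mask.  Voxel indices are 0-based in world-coordinate
#' computations (`voxel_to_world()`); all physics downstream is done in SI
#' units, with the mm-based affine converted where needed.
#'
#' @param data 3-D numeric array.
#' @param voxel_size length-3 positive numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform (mm).  Defaults to a scaled
#'   identity built from `voxel_size`.
#' @param mask logical array of the same shape; defaults to the finite
#'   voxels of `data`.  Non-finite values inside the mask are an error;
#'   non-finite values outside it are tolerated and flagged with a message.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                          mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3-D volume, got ", length(dim(data)), " dimension(s)")
  storage.mode(data) <- "double"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (mm)")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (is.null(mask)) mask <- is.finite(data)
  mask <- array(as.logical(mask), dim(data))
  if (!identical(dim(mask), dim(data)))
    stop("mask shape must equal data shape")
  bad <- sum(!is.finite(data[mask]))
  if (bad > 0L)
    stop("non-finite values inside mask at ", bad, " voxel(s)")
  if (any(!is.finite(data[!mask])))
    message("note: non-finite values outside the mask (tolerated)")
  structure(list(data = data, affine = affine, voxel_size = voxel_size,
                 mask = mask),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  v <- x$data[x$mask]
  cat(sprintf("  in-mask: %d voxels, range [%.4g, %.4g]\n",
              length(v), min(v), max(v)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

## world coordinates (mm) of 0-based voxel indices, rows of `ijk`
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind(ijk)
  h <- cbind(ijk, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(xyz)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE]
}

same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol &&
    max(abs(a$voxel_size - b$voxel_size)) <= tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' Read a scalar volume from a NIfTI file
#'
#' @param path NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param mask optional logical array overriding the default finite-value
#'   mask.
#' @return A [scalar_volume()].
#' @export
load_scalar_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected 3-D volume, got ", length(dim(arr)), "-D image")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  scalar_volume(array(as.numeric(arr), dim(arr)), voxel_size = vs,
                affine = aff, mask = mask)
}

#' Write a scalar volume to a NIfTI file
#'
#' Data are stored as float64 so that write/read round trips are exact.
#'
#' @param vol a [scalar_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, `"double"` (default) or `"float"`.
#' @return `path`, invisibly.
#' @export
write_scalar_volume <- function(vol, path, datatype = "double") {
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Symmetric tensor volume (6 unique components per voxel)
#'
#' Stores a field of symmetric 3x3 tensors as a 4-D array whose fourth
#' dimension holds the lower-triangular components in the order
#' `xx, xy, yy, xz, yz, zz` (the dialect used by all tensor NIfTI files
#' this package reads and writes).
#'
#' @param data 4-D numeric array with `dim[4] == 6`.
#' @inheritParams scalar_volume
#' @return An object of class `tensor_volume`.
#' @export
tensor_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                          mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L || dim(data)[4] != 6L)
    stop("tensor data must be a 4-D array with 6 components per voxel")
  storage.mode(data) <- "double"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  if (is.null(mask)) mask <- apply(is.finite(data), 1:3, all)
  mask <- array(as.logical(mask), dim(data)[1:3])
  structure(list(data = data, affine = as.matrix(affine),
                 voxel_size = voxel_size, mask = mask),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<tensor_volume> %d x %d x %d voxels (6 comps: xx,xy,yy,xz,yz,zz)\n",
    d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.tensor_volume <- function(x) dim(x$data)[1:3]

## order of the 6 stored components within a 3x3 symmetric matrix
.tensor_comp_index <- rbind(c(1, 1), c(1, 2), c(2, 2), c(1, 3), c(2, 3),
                            c(3, 3))

## 3x3 matrix of one voxel
tensor_at <- function(tv, i, j, k) {
  v <- tv$data[i, j, k, ]
  m <- matrix(0, 3, 3)
  for (q in 1:6) {
    m[.tensor_comp_index[q, 1], .tensor_comp_index[q, 2]] <- v[q]
    m[.tensor_comp_index[q, 2], .tensor_comp_index[q, 1]] <- v[q]
  }
  m
}

## pack a 3x3 symmetric matrix into the 6-vector dialect
tensor_pack <- function(m) {
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}

#' Read / write tensor volumes (NIfTI, 4-D with 6 components)
#'
#' @param path NIfTI file storing a 4-D image whose fourth dimension holds
#'   the six lower-triangular components `xx, xy, yy, xz, yz, zz`.
#' @param mask optional logical array.
#' @return A [tensor_volume()].
#' @export
load_tensor_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 6L)
    stop("expected a 4-D tensor volume with 6 components")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  tensor_volume(array(as.numeric(arr), dim(arr)), voxel_size = vs,
                affine = aff, mask = mask)
}

#' @rdname load_tensor_volume
#' @param tv a [tensor_volume()].
#' @export
write_tensor_volume <- function(tv, path) {
  img <- RNifti::asNifti(tv$data)
  RNifti::sform(img) <- structure(tv$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
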