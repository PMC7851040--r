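#' Voxel-wise eigendecomposition of a symmetric tensor field
#'
#' Solves `D E = E Lambda` in every in-mask voxel: eigenvalues are sorted
#' descending, eigenvectors are unit-norm and mutually orthogonal, and the
#' sign of each eigenvector is fixed by making its first nonzero component
#' positive so that tensor reassembly is reproducible.  Eigenvalues below
#' the floor `eps` are clamped to it, which guarantees that downstream
#' tensors built from the decomposition are positive definite even in
#' noisy voxels.
#'
#' @param tensor a [tensor_volume()]; each voxel must be symmetric (the
#'   storage is symmetric by construction; the check guards tensors
#'   assembled from external component maps).
#' @param eps eigenvalue floor, default `1e-12` (SI units).
#' @return An object of class `eigen_field` with `values` (array
#'   `nx x ny x nz x 3`, descending) and `vectors`
#'   (array `nx x ny x nz x 3 x 3`; `vectors[i,j,k, , q]` is the q-th
#'   eigenvector).
#' @export
eigendecompose <- function(tensor, eps = 1e-12) {
  stopifnot(inherits(tensor, "tensor_volume"))
  d <- dim(tensor$data)[1:3]
  vals <- array(0, c(d, 3))
  vecs <- array(0, c(d, 3, 3))
  vecs[, , , 1, 1] <- 1; vecs[, , , 2, 2] <- 1; vecs[, , , 3, 3] <- 1
  idx <- which(tensor$mask, arr.ind = TRUE)
  comp <- matrix(tensor$data, prod(d), 6)
  lin <- which(tensor$mask)
  for (q in seq_along(lin)) {
    v <- comp[lin[q], ]
    m <- matrix(c(v[1], v[2], v[4],
                  v[2], v[3], v[5],
                  v[4], v[5], v[6]), 3, 3)
    e <- eigen(m, symmetric = TRUE)
    lam <- pmax(e$values, eps)
    E <- e$vectors
    for (c_ in 1:3) {
      nz <- which(abs(E[, c_]) > 1e-12)[1]
      if (!is.na(nz) && E[nz, c_] < 0) E[, c_] <- -E[, c_]
    }
    i <- idx[q, 1]; j <- idx[q, 2]; k <- idx[q, 3]
    vals[i, j, k, ] <- lam
    vecs[i, j, k, , ] <- E
  }
  structure(list(values = vals, vectors = vecs, mask = tensor$mask,
                 voxel_size = tensor$voxel_size, affine = tensor$affine,
                 eps = eps),
            class = "eigen_field")
}

#' @export
print.eigen_field <- function(x, ...) {
  cat("<eigen_field> on", paste(dim(x$values)[1:3], collapse = " x "),
      "grid\n")
  invisible(x)
}

## single-voxel eigen decomposition used by tests and tensor builders
eigen_voxel <- function(m, eps = 1e-12, tol = 1e-8) {
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop("tensor is not symmetric beyond tolerance ", tol)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  E <- e$vectors
  for (c_ in 1:3) {
    nz <- which(abs(E[, c_]) > 1e-12)[1]
    if (!is.na(nz) && E[nz, c_] < 0) E[, c_] <- -E[, c_]
  }
  list(values = pmax(e$values, eps), vectors = E)
}

#' Fractional anisotropy of an eigenvalue field
#'
#' Computes the standard fractional anisotropy
#' \deqn{FA = \sqrt{3/2}\,\frac{\| \lambda - \bar\lambda \|}
#'                          {\| \lambda \|}}
#' per voxel, a scalar in `[0, 1]` that is 0 for isotropic diffusion and
#' approaches 1 when one eigenvalue dominates.  The FA of an all-zero
#' eigenvalue triple is defined as 0 (such voxels are background or CSF).
#'
#' @param eig an [eigendecompose()] result.
#' @return A [scalar_volume()] of FA values.
#' @export
compute_fa <- function(eig) {
  stopifnot(inherits(eig, "eigen_field"))
  d <- dim(eig$values)[1:3]
  l1 <- array(eig$values[, , , 1], d)
  l2 <- array(eig$values[, , , 2], d)
  l3 <- array(eig$values[, , , 3], d)
  fa <- array(fa_from_lambdas(l1, l2, l3), d)
  scalar_volume(fa, voxel_size = eig$voxel_size, affine = eig$affine,
                mask = eig$mask)
}

fa_from_lambdas <- function(l1, l2, l3) {
  lbar <- (l1 + l2 + l3) / 3
  num <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(num / pmax(den, .Machine$double.xmin))
  fa[den == 0] <- 0
  pmin(fa, 1)
}

## assemble E diag(lam) E^T
tensor_from_eigen <- function(E, lam) {
  E %*% (lam * t(E))
}
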