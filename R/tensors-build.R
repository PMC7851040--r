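#' Build the voxel-wise diffusivity tensor field
#'
#' Grey-matter voxels receive the isotropic tracer diffusivity
#' \eqn{D_{GM} = D_0 I}.  White-matter voxels receive the
#' water-diffusion eigenstructure rescaled to the tracer's molecular
#' diffusivity,
#' \deqn{D_{WM} = \frac{D_0}{\bar\lambda}\, E\,\Lambda\,E^T, \qquad
#'       \bar\lambda = \tfrac13\sum_i \lambda_i,}
#' so that the trace of every white-matter voxel equals `3 D0` exactly
#' while the anisotropy and principal directions of the measured tensor
#' are preserved.  CSF voxels receive the isotropic CSF diffusivity from
#' [csf_properties()].
#'
#' @param labels a [segment_tissue()] result.
#' @param eig an [eigendecompose()] result defined on all white-matter
#'   voxels.
#' @param constants [tissue_constants()].
#' @param csf values from [csf_properties()]; used for CSF voxels.
#' @return A [tensor_volume()] in m^2/s.
#' @export
build_diffusivity <- function(labels, eig, constants = tissue_constants(),
                              csf = csf_properties()) {
  stopifnot(inherits(labels, "tissue_labels"),
            inherits(eig, "eigen_field"))
  d <- dim(labels$labels)
  out <- array(0, c(d, 6))
  D0 <- constants$D0
  iso_rows <- tensor_pack(diag(3))
  set_iso <- function(arr, which_vox, value) {
    for (q in 1:6) {
      comp <- arr[, , , q]
      comp[which_vox] <- value * iso_rows[q]
      arr[, , , q] <- comp
    }
    arr
  }
  out <- set_iso(out, labels$labels == 1L, D0)
  out <- set_iso(out, labels$labels == 3L, csf$D_csf)
  wm <- which(labels$labels == 2L, arr.ind = TRUE)
  for (q in seq_len(nrow(wm))) {
    i <- wm[q, 1]; j <- wm[q, 2]; k <- wm[q, 3]
    lam <- eig$values[i, j, k, ]
    lbar <- mean(lam)
    if (lbar <= 0)
      stop(sprintf("WM voxel (%d,%d,%d) has non-positive mean eigenvalue",
                   i, j, k))
    E <- eig$vectors[i, j, k, , ]
    out[i, j, k, ] <- tensor_pack(tensor_from_eigen(E, D0 * lam / lbar))
  }
  tensor_volume(out, voxel_size = labels$voxel_size,
                affine = labels$affine, mask = labels$mask)
}

#' Build the voxel-wise hydraulic permeability tensor field
#'
#' Grey matter is isotropic, \eqn{K_{GM} = K_0 I}.  White matter is
#' transversely isotropic about the principal fibre direction `e1`,
#' \deqn{K_{WM} = E\,\mathrm{diag}(k_\parallel, k_\perp, k_\perp)\,E^T,}
#' with the eigenvalues either evaluated from the microstructure laws at
#' the voxel's extracellular fraction (`mode = "noddi"`, requires
#' `noddi`) or fixed at the DTI-baseline constants
#' (`mode = "constant"`, `noddi` ignored).  `vf_ecs` values outside the
#' law's calibration range are clamped to its edges; the number of
#' clamped white-matter voxels is attached as attribute
#' `clamped_voxels`.
#'
#' @param labels a [segment_tissue()] result.
#' @param eig an [eigendecompose()] result supplying `E` on white matter.
#' @param noddi a `noddi_maps` object, or `NULL` in constant mode.
#' @param law a [permeability_law()].
#' @param constants [tissue_constants()].
#' @param csf values from [csf_properties()].
#' @return A [tensor_volume()] in m^2, with attribute `clamped_voxels`.
#' @export
build_permeability <- function(labels, eig, noddi = NULL,
                               law = permeability_law("constant"),
                               constants = tissue_constants(),
                               csf = csf_properties()) {
  stopifnot(inherits(labels, "tissue_labels"),
            inherits(eig, "eigen_field"),
            inherits(law, "permeability_law"))
  if (law$mode == "noddi" && is.null(noddi))
    stop("mode = 'noddi' requires NODDI maps")
  d <- dim(labels$labels)
  out <- array(0, c(d, 6))
  iso_rows <- tensor_pack(diag(3))
  for (q in 1:6) {
    comp <- out[, , , q]
    comp[labels$labels == 1L] <- constants$K0 * iso_rows[q]
    comp[labels$labels == 3L] <- csf$K_csf * iso_rows[q]
    out[, , , q] <- comp
  }
  wm <- which(labels$labels == 2L, arr.ind = TRUE)
  clamped <- 0L
  for (q in seq_len(nrow(wm))) {
    i <- wm[q, 1]; j <- wm[q, 2]; k <- wm[q, 3]
    if (law$mode == "noddi") {
      v <- noddi$vf_ecs$data[i, j, k]
      if (!is.finite(v))
        stop(sprintf("vf_ecs missing on WM voxel (%d,%d,%d)", i, j, k))
      if (v < law$clamp_range[1] || v > law$clamp_range[2])
        clamped <- clamped + 1L
      ks <- law_eigenvalues(law, v)
    } else {
      ks <- law_eigenvalues(law)
    }
    E <- eig$vectors[i, j, k, , ]
    out[i, j, k, ] <- tensor_pack(tensor_from_eigen(E, c(ks[1], ks[2],
                                                         ks[2])))
  }
  tv <- tensor_volume(out, voxel_size = labels$voxel_size,
                      affine = labels$affine, mask = labels$mask)
  attr(tv, "clamped_voxels") <- clamped
  if (clamped > 0L)
    message("vf_ecs clamped to the law range in ", clamped,
            " WM voxel(s)")
  tv
}

#' Isotropic CSF transport properties
#'
#' CSF transport constants are not part of the calibrated tissue model;
#' they are exposed as configuration with documented defaults: the tracer
#' molecular diffusivity for `D_csf` and a high isotropic permeability
#' `K_csf = 1e-13` m^2 reflecting free fluid.  The infusion simulator
#' warns whenever the infusion volume touches a CSF voxel, since the
#' validation phantoms (like the calibrated model itself) confine the
#' infusion to white matter.
#'
#' @param D_csf CSF diffusivity (m^2/s).
#' @param K_csf CSF permeability (m^2).
#' @return A list with elements `D_csf` and `K_csf`.
#' @export
csf_properties <- function(D_csf = tissue_constants()$D0, K_csf = 1e-13) {
  stopifnot(D_csf > 0, K_csf > 0)
  list(D_csf = D_csf, K_csf = K_csf)
}
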