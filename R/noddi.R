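#' NODDI compartment maps and the extracellular volume fraction
#'
#' The NODDI tissue model yields, per voxel, the intraneurite volume
#' fraction (`ficvf`, conditional on the non-CSF tissue) and the isotropic
#' free-water fraction (`fiso`).  `reparameterize_noddi()` converts these
#' raw toolbox outputs into three absolute compartment fractions that sum
#' to one in every voxel,
#' \deqn{VF_{INC} = f_{icvf}(1 - f_{iso}), \quad
#'       VF_{ENC} = (1 - f_{icvf})(1 - f_{iso}), \quad
#'       VF_{Water} = f_{iso},}
#' and derives the extracellular-space fraction
#' \eqn{VF_{ECS} = VF_{ENC} + VF_{Water}} — the space where an infused
#' drug can actually flow and the independent variable of the
#' white-matter permeability laws ([k_parallel()], [k_perpendicular()]).
#'
#' @param vf_inc_raw [scalar_volume()] of raw intraneurite fractions
#'   (`ficvf`), values in `[0, 1]`.
#' @param vf_water [scalar_volume()] of isotropic/CSF fractions (`fiso`),
#'   same grid, values in `[0, 1]`.
#' @param tol tolerance on the `[0, 1]` range check.
#' @return An object of class `noddi_maps`: a list of scalar volumes
#'   `vf_inc`, `vf_enc`, `vf_water`, `vf_ecs`.
#' @export
reparameterize_noddi <- function(vf_inc_raw, vf_water, tol = 1e-6) {
  stopifnot(inherits(vf_inc_raw, "scalar_volume"),
            inherits(vf_water, "scalar_volume"))
  stop_if_grid_mismatch(vf_inc_raw, vf_water)
  mask <- vf_inc_raw$mask & vf_water$mask
  check_unit_range <- function(v, name) {
    x <- v$data[mask]
    if (any(x < -tol | x > 1 + tol))
      stop(name, " has values outside [0, 1] beyond tolerance ", tol)
  }
  check_unit_range(vf_inc_raw, "vf_inc_raw")
  check_unit_range(vf_water, "vf_water")
  ficvf <- pmin(pmax(vf_inc_raw$data, 0), 1)
  fiso <- pmin(pmax(vf_water$data, 0), 1)
  mk <- function(x) scalar_volume(array(x, dim(ficvf)),
                                  voxel_size = vf_inc_raw$voxel_size,
                                  affine = vf_inc_raw$affine, mask = mask)
  vf_inc <- ficvf * (1 - fiso)
  vf_enc <- (1 - ficvf) * (1 - fiso)
  out <- list(vf_inc = mk(vf_inc), vf_enc = mk(vf_enc),
              vf_water = mk(fiso), vf_ecs = mk(vf_enc + fiso))
  class(out) <- "noddi_maps"
  out
}

#' Assemble NODDI maps from already-absolute compartment fractions
#'
#' Used by the phantom generator and by readers of pre-reparameterized
#' data.  Checks the sum-to-one invariant and derives `vf_ecs`.
#'
#' @param vf_inc,vf_enc,vf_water scalar volumes of absolute compartment
#'   fractions on one grid.
#' @param tol tolerance on `vf_inc + vf_enc + vf_water == 1`.
#' @return A `noddi_maps` object.
#' @export
noddi_maps <- function(vf_inc, vf_enc, vf_water, tol = 1e-6) {
  stop_if_grid_mismatch(vf_inc, vf_enc)
  stop_if_grid_mismatch(vf_inc, vf_water)
  mask <- vf_inc$mask & vf_enc$mask & vf_water$mask
  s <- vf_inc$data[mask] + vf_enc$data[mask] + vf_water$data[mask]
  if (any(abs(s - 1) > tol))
    stop("compartment fractions do not sum to 1 (max |sum-1| = ",
         format(max(abs(s - 1))), ")")
  ecs <- scalar_volume(vf_enc$data + vf_water$data,
                       voxel_size = vf_inc$voxel_size,
                       affine = vf_inc$affine, mask = mask)
  structure(list(vf_inc = vf_inc, vf_enc = vf_enc, vf_water = vf_water,
                 vf_ecs = ecs),
            class = "noddi_maps")
}

#' @export
print.noddi_maps <- function(x, ...) {
  m <- x$vf_ecs$mask
  cat("<noddi_maps> compartment fractions on",
      paste(dim(x$vf_ecs$data), collapse = " x "), "grid\n")
  cat(sprintf("  VF_ECS in-mask range [%.3f, %.3f]\n",
              min(x$vf_ecs$data[m]), max(x$vf_ecs$data[m])))
  invisible(x)
}
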