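#' Physical constants of the brain-tissue transport model
#'
#' All constants are stored in SI units; the constructor performs the unit
#' conversions once, so every other function in the package can assume SI.
#'
#' Defaults:
#' * `D0` — apparent molecular diffusivity of the gadolinium tracer,
#'   1.54e-6 cm^2/s = 1.54e-10 m^2/s;
#' * `K0` — isotropic grey-matter permeability, 4.22e-18 m^2;
#' * `k_par_dti`, `k_perp_dti` — the constant white-matter permeability
#'   eigenvalues of the DTI baseline model, 6.75e-15 and 4.22e-16 m^2;
#' * `r_axon` — axon radius of the fibre-lattice microstructure model,
#'   0.34 um;
#' * `fa_gm_wm` — FA threshold separating grey and white matter, 0.23;
#' * `vf_water_csf` — free-water fraction above which a voxel is CSF,
#'   0.99.
#'
#' @param D0_cm2_s diffusivity in cm^2/s.
#' @param K0,k_par_dti,k_perp_dti permeabilities in m^2.
#' @param r_axon_um axon radius in micrometres.
#' @param fa_gm_wm,vf_water_csf segmentation thresholds, in (0, 1).
#' @return A `tissue_constants` list (SI units).
#' @export
tissue_constants <- function(D0_cm2_s = 1.54e-6,
                             K0 = 4.22e-18,
                             k_par_dti = 6.75e-15,
                             k_perp_dti = 4.22e-16,
                             r_axon_um = 0.34,
                             fa_gm_wm = 0.23,
                             vf_water_csf = 0.99) {
  out <- list(D0 = cm2_s_to_m2_s(D0_cm2_s),
              K0 = K0,
              k_par_dti = k_par_dti,
              k_perp_dti = k_perp_dti,
              r_axon = um_to_m(r_axon_um),
              fa_gm_wm = fa_gm_wm,
              vf_water_csf = vf_water_csf)
  if (any(unlist(out) <= 0)) stop("all tissue constants must be positive")
  if (fa_gm_wm <= 0 || fa_gm_wm >= 1 || vf_water_csf <= 0 ||
      vf_water_csf >= 1)
    stop("segmentation thresholds must lie in (0, 1)")
  class(out) <- "tissue_constants"
  out
}

#' @export
print.tissue_constants <- function(x, ...) {
  cat("<tissue_constants> (SI)\n")
  cat(sprintf("  D0 = %.3g m^2/s, K0 = %.3g m^2\n", x$D0, x$K0))
  cat(sprintf("  DTI baseline k_par = %.3g, k_perp = %.3g m^2\n",
              x$k_par_dti, x$k_perp_dti))
  cat(sprintf("  axon radius = %.3g m; FA(GM/WM) = %.2f; VF_Water(CSF) = %.2f\n",
              x$r_axon, x$fa_gm_wm, x$vf_water_csf))
  invisible(x)
}

## ---- unit conversions (one place, unit-tested) -------------------------

cm2_s_to_m2_s <- function(x) x * 1e-4

um_to_m <- function(x) x * 1e-6

mm_to_m <- function(x) x * 1e-3

#' Unit conversions used throughout the package
#'
#' Small, explicit helpers: infusion rates in uL/min to m^3/s and
#' first-order loss rates in 1/min to 1/s.
#'
#' @param x value to convert.
#' @return The converted value.
#' @export
ul_min_to_m3_s <- function(x) x * 1e-9 / 60

#' @rdname ul_min_to_m3_s
#' @export
per_min_to_per_s <- function(x) x / 60

#' @rdname ul_min_to_m3_s
#' @export
mol_L_to_mol_m3 <- function(x) x * 1e3
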