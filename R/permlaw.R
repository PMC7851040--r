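#' Microstructure-based white-matter permeability laws
#'
#' Closed-form hydraulic permeabilities of an aligned fibre bundle as a
#' function of the extracellular volume fraction `vf_ecs`, obtained by
#' fitting homogenised unit-cell flow simulations (see
#' [microscale_sweep()]) with the Tamayol–Bahrami functional form for
#' flow parallel to the fibres and the Kuwabara form for flow
#' perpendicular to them.  With the solid fraction
#' \eqn{\varphi = 1 - VF_{ECS}}:
#' \deqn{k_\parallel = \frac{r^2}{c_0 \varphi}\left(c_1 + c_2\ln\varphi +
#'   c_3\varphi + c_4\varphi^2 + c_5\varphi^4\right)}
#' with default coefficients (2.97, -1.47, -0.94, 2, -0.5, -0.039), and
#' \deqn{k_\perp = \frac{r^2}{c_0 \varphi}\left(c_1 + c_2\ln\varphi +
#'   c_3\varphi + c_4\varphi^2\right)}
#' with default coefficients (7.77, -1.56, -1.04, 2.05, -0.5).
#'
#' The laws were calibrated on `vf_ecs` in `[0.15, 0.80]`; inputs outside
#' that range are clamped to its edges (the number of clamped voxels is
#' reported by the tensor builders).  Note that with its default
#' coefficients the perpendicular law changes sign near
#' `vf_ecs ~ 0.295`: the printed closed form is negative below that
#' value, a property of the published coefficients that users evaluating
#' `k_perp` at low `vf_ecs` should be aware of.
#'
#' @param vf_ecs extracellular volume fraction(s), clamped to
#'   `clamp_range`.
#' @param r fibre (axon) radius in metres; must be positive.
#' @param coef law coefficients `(c0, c1, c2, c3, c4[, c5])`; defaults are
#'   the calibrated values above.
#' @param clamp_range fitted validity range of the law.
#' @return Permeability in m^2 (vectorised over `vf_ecs`).
#' @export
k_parallel <- function(vf_ecs, r = tissue_constants()$r_axon,
                       coef = c(2.97, -1.47, -0.94, 2, -0.5, -0.039),
                       clamp_range = c(0.15, 0.80)) {
  if (any(r <= 0)) stop("fibre radius must be positive")
  v <- pmin(pmax(vf_ecs, clamp_range[1]), clamp_range[2])
  phi <- 1 - v
  r^2 / (coef[1] * phi) *
    (coef[2] + coef[3] * log(phi) + coef[4] * phi + coef[5] * phi^2 +
       coef[6] * phi^4)
}

#' @rdname k_parallel
#' @export
k_perpendicular <- function(vf_ecs, r = tissue_constants()$r_axon,
                            coef = c(7.77, -1.56, -1.04, 2.05, -0.5),
                            clamp_range = c(0.15, 0.80)) {
  if (any(r <= 0)) stop("fibre radius must be positive")
  v <- pmin(pmax(vf_ecs, clamp_range[1]), clamp_range[2])
  phi <- 1 - v
  r^2 / (coef[1] * phi) *
    (coef[2] + coef[3] * log(phi) + coef[4] * phi + coef[5] * phi^2)
}

#' Permeability-law object
#'
#' Bundles the axon radius, the mode (`"noddi"` for the
#' microstructure-dependent laws, `"constant"` for the fixed DTI baseline
#' eigenvalues) and the law coefficients, as consumed by
#' [build_permeability()].
#'
#' @param mode `"noddi"` or `"constant"`.
#' @param r fibre radius (m).
#' @param coef_parallel,coef_perpendicular law coefficients.
#' @param clamp_range validity range of `vf_ecs` for the laws.
#' @param constants [tissue_constants()] supplying the fixed baseline
#'   eigenvalues in `"constant"` mode.
#' @return An object of class `permeability_law`.
#' @export
permeability_law <- function(mode = c("noddi", "constant"),
                             r = tissue_constants()$r_axon,
                             coef_parallel = c(2.97, -1.47, -0.94, 2,
                                               -0.5, -0.039),
                             coef_perpendicular = c(7.77, -1.56, -1.04,
                                                    2.05, -0.5),
                             clamp_range = c(0.15, 0.80),
                             constants = tissue_constants()) {
  mode <- match.arg(mode)
  structure(list(mode = mode, r = r, coef_parallel = coef_parallel,
                 coef_perpendicular = coef_perpendicular,
                 clamp_range = clamp_range, constants = constants),
            class = "permeability_law")
}

#' @export
print.permeability_law <- function(x, ...) {
  cat("<permeability_law> mode =", x$mode, "\n")
  if (x$mode == "noddi") {
    cat("  parallel coefs:      ",
        paste(signif(x$coef_parallel, 4), collapse = ", "), "\n")
    cat("  perpendicular coefs: ",
        paste(signif(x$coef_perpendicular, 4), collapse = ", "), "\n")
    cat("  vf_ecs clamp range:  [", x$clamp_range[1], ",",
        x$clamp_range[2], "]\n")
  } else {
    cat(sprintf("  fixed k_par = %.3g m^2, k_perp = %.3g m^2\n",
                x$constants$k_par_dti, x$constants$k_perp_dti))
  }
  invisible(x)
}

## evaluate (k_par, k_perp) for one voxel under a law
law_eigenvalues <- function(law, vf_ecs = NA_real_) {
  if (law$mode == "constant")
    return(c(law$constants$k_par_dti, law$constants$k_perp_dti))
  if (is.na(vf_ecs))
    stop("vf_ecs required for mode = 'noddi'")
  c(k_parallel(vf_ecs, law$r, law$coef_parallel, law$clamp_range),
    k_perpendicular(vf_ecs, law$r, law$coef_perpendicular,
                    law$clamp_range))
}
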