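#' Run one full infusion case
#'
#' Orchestrates the whole pipeline for one catheter set-up: segment
#' tissue from FA and free water, eigendecompose the measured diffusion
#' tensor, build the tracer diffusivity and hydraulic permeability
#' tensor fields (microstructure-dependent `"noddi"` mode or
#' constant-eigenvalue `"dti"` baseline), solve the steady Darcy problem
#' and integrate the transport equation.  A provenance record (all
#' constants, mode, package version) is attached to the result.
#'
#' @param tensor measured water-diffusion [tensor_volume()].
#' @param fa [scalar_volume()] of fractional anisotropy.
#' @param noddi a `noddi_maps` object (supplies free water for
#'   segmentation and `vf_ecs` for the permeability laws).
#' @param catheter a [catheter_spec()].
#' @param config a [simulation_config()].
#' @param mode `"noddi"` (microstructure-dependent permeability) or
#'   `"dti"` (constant white-matter permeability eigenvalues).
#' @param constants [tissue_constants()].
#' @param csf [csf_properties()].
#' @param output_times snapshot times (s); default the total time.
#' @param mask optional mask override.
#' @return An object of class `ced_result` bundling the tensor fields,
#'   the Darcy solution, the transport snapshots, the tissue labels and
#'   the provenance record.
#' @export
run_case <- function(tensor, fa, noddi, catheter,
                     config = simulation_config(),
                     mode = c("noddi", "dti"),
                     constants = tissue_constants(),
                     csf = csf_properties(), output_times = NULL,
                     mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "tensor_volume"),
            inherits(fa, "scalar_volume"),
            inherits(noddi, "noddi_maps"))
  labels <- segment_tissue(fa, noddi$vf_water, constants)
  eig <- eigendecompose(tensor)
  Dfield <- build_diffusivity(labels, eig, constants, csf)
  law <- if (mode == "noddi") permeability_law("noddi",
                                               r = constants$r_axon,
                                               constants = constants)
  else permeability_law("constant", constants = constants)
  K <- build_permeability(labels, eig,
                          noddi = if (mode == "noddi") noddi,
                          law = law, constants = constants, csf = csf)
  if (!is.null(mask)) { K$mask <- mask; Dfield$mask <- mask }
  darcy <- solve_pressure(K, catheter, config)
  src <- darcy$source_voxels
  if (any(labels$labels[src] != 2L))
    warning("catheter tip voxel(s) are not white matter")
  transport <- solve_transport(darcy, Dfield, catheter, config,
                               output_times = output_times)
  final <- transport$conc[[length(transport$conc)]]
  reg <- infusion_region(final, c0 = catheter$c0_si,
                         c_min_fraction = config$c_min_fraction)
  if (reg$n > 0 && any(labels$labels[reg$voxels] == 3L))
    warning("infusion volume touches CSF voxel(s)")
  prov <- list(mode = mode, constants = unclass(constants),
               csf = csf, law = unclass(law)[c("mode", "coef_parallel",
                                               "coef_perpendicular",
                                               "clamp_range")],
               catheter = unclass(catheter),
               config = unclass(config),
               clamped_voxels = attr(K, "clamped_voxels"),
               package_version =
                 as.character(utils::packageVersion("cedflow")),
               timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(mode = mode, labels = labels, diffusivity = Dfield,
                 permeability = K, darcy = darcy,
                 transport = transport, catheter = catheter,
                 config = config, region = reg, provenance = prov),
            class = "ced_result")
}

#' @export
print.ced_result <- function(x, ...) {
  cat("<ced_result> mode =", x$mode, "\n")
  print(x$transport)
  cat(sprintf("  infusion volume (c > %.3g%% c0): %.3g mm^3 (%d voxels)\n",
              100 * x$config$c_min_fraction, x$region$volume,
              x$region$n))
  invisible(x)
}

#' @export
summary.ced_result <- function(object, ...) {
  reg <- object$region
  out <- list(mode = object$mode,
              infusion_volume_mm3 = reg$volume,
              n_voxels = reg$n,
              principal_direction = if (reg$n >= 2)
                principal_direction(reg) else rep(NA_real_, 3),
              budget = object$transport$budget,
              mass_balance_error = object$darcy$mass_balance_error)
  class(out) <- "summary.ced_result"
  out
}

#' @export
print.summary.ced_result <- function(x, ...) {
  cat("CED simulation summary (mode =", x$mode, ")\n")
  cat(sprintf("  infusion volume: %.3g mm^3 in %d voxels\n",
              x$infusion_volume_mm3, x$n_voxels))
  if (!anyNA(x$principal_direction))
    cat(sprintf("  principal direction: (%.3f, %.3f, %.3f)\n",
                x$principal_direction[1], x$principal_direction[2],
                x$principal_direction[3]))
  cat(sprintf("  Darcy mass balance error: %.2e\n",
              x$mass_balance_error))
  print(x$budget, row.names = FALSE)
  invisible(x)
}

#' Paired simulations over the nine standard catheter orientations
#'
#' Runs both permeability models for each of the nine catheter
#' orientations of [catheter_orientations()], returning paired results
#' for the comparison metrics.
#'
#' @inheritParams run_case
#' @param tip catheter tip world coordinates (mm), shared by all nine
#'   orientations.
#' @param ... passed to [run_case()].
#' @return A list of nine elements, each with `orientation`, `noddi`
#'   and `dti` (`ced_result`) entries.
#' @export
nine_orientation_suite <- function(tensor, fa, noddi, tip,
                                   config = simulation_config(), ...) {
  ors <- catheter_orientations()
  out <- vector("list", nrow(ors))
  for (q in seq_len(nrow(ors))) {
    cath <- catheter_spec(tip, orientation = ors[q, ])
    out[[q]] <- list(orientation = ors[q, ],
                     noddi = run_case(tensor, fa, noddi, cath, config,
                                      mode = "noddi", ...),
                     dti = run_case(tensor, fa, noddi, cath, config,
                                    mode = "dti", ...))
  }
  names(out) <- rownames(ors)
  out
}
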