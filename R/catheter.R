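#' Catheter specification
#'
#' Geometry and infusion parameters of the delivery catheter.  The
#' sub-voxel catheter is represented in the solver as a volumetric
#' fluid-and-solute source distributed over the voxel(s) intersected by
#' the tip face (a disk of the catheter diameter normal to the
#' orientation); the orientation vector is recorded for the shape
#' metrics.
#'
#' @param tip length-3 world coordinates of the tip (mm).
#' @param orientation length-3 direction of the catheter axis; normalised
#'   internally, must be nonzero.
#' @param diameter catheter diameter (m); default 1 mm.
#' @param flow_rate infusion rate (m^3/s); default 3 uL/min.
#' @param c0 inlet concentration (mol/L); default 0.5.
#' @return An object of class `catheter_spec`.  `c0_si` holds the inlet
#'   concentration in mol/m^3.
#' @export
catheter_spec <- function(tip, orientation = c(1, 0, 0),
                          diameter = 1e-3,
                          flow_rate = ul_min_to_m3_s(3), c0 = 0.5) {
  tip <- as.numeric(tip); orientation <- as.numeric(orientation)
  stopifnot(length(tip) == 3L, length(orientation) == 3L)
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("orientation must be a nonzero vector")
  if (flow_rate <= 0) stop("flow rate must be positive")
  if (diameter <= 0) stop("diameter must be positive")
  structure(list(tip = tip, orientation = orientation / nrm,
                 diameter = diameter, flow_rate = flow_rate, c0 = c0,
                 c0_si = mol_L_to_mol_m3(c0)),
            class = "catheter_spec")
}

#' @export
print.catheter_spec <- function(x, ...) {
  cat(sprintf(
    "<catheter_spec> tip (%.4g, %.4g, %.4g) mm, axis (%.3f, %.3f, %.3f)\n",
    x$tip[1], x$tip[2], x$tip[3], x$orientation[1], x$orientation[2],
    x$orientation[3]))
  cat(sprintf("  d = %.3g m, Q = %.3g m^3/s, c0 = %.3g mol/L\n",
              x$diameter, x$flow_rate, x$c0))
  invisible(x)
}

#' Simulation configuration
#'
#' Physical and numerical settings of the infusion simulation, in SI
#' units.
#'
#' @param mu interstitial-fluid viscosity (Pa s).
#' @param loss_rate_per_min first-order tracer loss (absorption/washout)
#'   rate in 1/min; converted to 1/s internally.
#' @param total_time infusion duration (s).
#' @param dt target time step (s); the solver sub-steps automatically
#'   whenever stability requires a smaller step.
#' @param cfl advective/diffusive stability safety factor in (0, 1].
#' @param c_min_fraction infusion-volume concentration threshold as a
#'   fraction of the inlet concentration.
#' @param limiter advective flux reconstruction: `"none"` (first-order
#'   upwind, provably bounded, the default) or `"vanleer"` (second-order
#'   MUSCL/TVD reconstruction, much less numerically diffusive; used for
#'   grid-convergence studies).
#' @param cross_tol,max_cross_iter convergence control of the
#'   deferred-correction iteration handling off-diagonal tensor fluxes
#'   in the pressure solve.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(mu = 1e-3, loss_rate_per_min = 0.01,
                              total_time = 180, dt = 1, cfl = 0.5,
                              c_min_fraction = 0.025,
                              limiter = c("none", "vanleer"),
                              cross_tol = 1e-8,
                              max_cross_iter = 60L) {
  limiter <- match.arg(limiter)
  stopifnot(mu > 0, loss_rate_per_min >= 0, total_time > 0, dt > 0,
            cfl > 0, cfl <= 1,
            c_min_fraction > 0, c_min_fraction < 1)
  structure(list(mu = mu,
                 loss_rate = per_min_to_per_s(loss_rate_per_min),
                 loss_rate_per_min = loss_rate_per_min,
                 total_time = total_time, dt = dt, cfl = cfl,
                 c_min_fraction = c_min_fraction, limiter = limiter,
                 cross_tol = cross_tol,
                 max_cross_iter = as.integer(max_cross_iter)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> mu = %.3g Pa s, loss = %.3g 1/s, T = %g s, dt = %g s\n",
    x$mu, x$loss_rate, x$total_time, x$dt))
  invisible(x)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file holds any subset of the [simulation_config()],
#' [tissue_constants()] and [catheter_spec()] fields under the top-level
#' keys `config`, `constants` and `catheter`; missing entries keep their
#' defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A list with elements `config`, `constants`, `catheter`
#'   (catheter may be `NULL` if unspecified).
#' @export
load_simulation_setup <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- do.call(simulation_config, as.list(raw$config %||% list()))
  con <- do.call(tissue_constants, as.list(raw$constants %||% list()))
  cath <- if (!is.null(raw$catheter))
    do.call(catheter_spec, as.list(raw$catheter))
  list(config = cfg, constants = con, catheter = cath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The nine standard catheter orientations
#'
#' Unit vectors of the nine-injection protocol: two antiparallel pairs
#' along the x and y axes in the sagittal/coronal planes, the
#' plane-intersection direction (z), and the four solid-angle bisectors
#' of the upper octants (components of magnitude `1/sqrt(3)`).
#'
#' @return A 9 x 3 matrix of unit row vectors.
#' @export
catheter_orientations <- function() {
  s <- 1 / sqrt(3)
  m <- rbind(c(1, 0, 0),      # 1: sagittal plane, +x
             c(0, 1, 0),      # 2: coronal plane, +y
             c(-1, 0, 0),     # 3: sagittal plane, -x
             c(0, -1, 0),     # 4: coronal plane, -y
             c(0, 0, 1),      # 5: plane intersection
             c(-s, -s, s),    # 6: bisector of [-x, -y, z]
             c(s, -s, s),     # 7: bisector of [x, -y, z]
             c(s, s, s),      # 8: bisector of [x, y, z]
             c(-s, s, s))     # 9: bisector of [-x, y, z]
  rownames(m) <- paste0("catheter", 1:9)
  m
}
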