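#' Synthetic DTI/NODDI phantom specification
#'
#' Describes a synthetic test object emulating the products of a
#' DTI + NODDI acquisition: a diffusion-tensor volume, an FA map,
#' compartment-fraction maps that sum to one, and a brain mask — all
#' with known ground truth.  Scenarios:
#' * `uniform_wm_slab` — homogeneous white matter with a constant fibre
#'   direction;
#' * `curved_bundle` — white matter whose fibre directions follow
#'   circular arcs in the xy-plane ([curved_bundle_field()]);
#' * `three_tissue` — white matter, grey matter and CSF slabs stacked
#'   along z.
#'
#' @param scenario phantom scenario.
#' @param shape grid shape (voxels).
#' @param voxel_size voxel edge (mm), default 2 mm isotropic.
#' @param fa_wm white-matter FA target (must exceed the WM threshold
#'   0.23).
#' @param fa_gm grey-matter FA target (below 0.23).
#' @param vf_ecs extracellular fraction of the white matter, either a
#'   single value or `c(lo, hi)` for a linear gradient along z; must lie
#'   within the permeability-law range `[0.15, 0.80]`.
#' @param vf_water white-matter free-water fraction (well below the CSF
#'   threshold).
#' @param fibre_direction constant WM fibre direction
#'   (`uniform_wm_slab`).
#' @param curvature arc curvature in 1/mm (`curved_bundle`); 0 gives a
#'   straight bundle.
#' @param noise standard deviation of additive Gaussian perturbations
#'   applied to the scalar maps (clipped back to valid ranges).
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(scenario = c("uniform_wm_slab", "curved_bundle",
                                      "three_tissue"),
                         shape = c(32, 32, 32), voxel_size = 2,
                         fa_wm = 0.7, fa_gm = 0.1, vf_ecs = 0.30,
                         vf_water = 0.05,
                         fibre_direction = c(1, 0, 0),
                         curvature = 0.02, noise = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (fa_wm <= 0.23 || fa_wm >= 1)
    stop("requested WM FA inconsistent with tissue class (need 0.23 < FA < 1)")
  if (fa_gm < 0 || fa_gm > 0.23)
    stop("requested GM FA inconsistent with tissue class (need FA <= 0.23)")
  if (any(vf_ecs < 0.15 | vf_ecs > 0.80))
    stop("vf_ecs must lie within the permeability-law range [0.15, 0.80]")
  if (any(vf_ecs - vf_water < 0))
    stop("vf_ecs must be at least vf_water")
  structure(list(scenario = scenario, shape = as.integer(shape),
                 voxel_size = voxel_size, fa_wm = fa_wm, fa_gm = fa_gm,
                 vf_ecs = vf_ecs, vf_water = vf_water,
                 fibre_direction = fibre_direction /
                   sqrt(sum(fibre_direction^2)),
                 curvature = curvature, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## transverse/principal eigenvalue ratio realising a target FA for a
## prolate tensor (l1, t l1, t l1): FA = (1 - t) / sqrt(1 + 2 t^2)
fa_to_eigenratio <- function(fa) {
  if (fa == 0) return(1)
  a <- 2 * fa^2 - 1
  if (abs(a) < 1e-12) return(0.25)
  t <- (-1 + sqrt(pmax(1 - a * (fa^2 - 1), 0))) / a
  min(max(t, 0), 1)
}

#' Curved fibre-orientation field
#'
#' Per-voxel unit fibre directions following circular arcs of the given
#' curvature in the xy-plane (a bent white-matter bundle); zero
#' curvature gives a constant field along x.
#'
#' @param shape grid shape.
#' @param voxel_size voxel edge (mm).
#' @param curvature arc curvature (1/mm).
#' @return Array `nx x ny x nz x 3` of unit vectors.
#' @export
curved_bundle_field <- function(shape, voxel_size = 2,
                                curvature = 0.02) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  d <- as.integer(shape)
  out <- array(0, c(d, 3))
  if (curvature == 0) {
    out[, , , 1] <- 1
    return(out)
  }
  R <- 1 / curvature
  cx <- (d[1] - 1) / 2 * voxel_size[1]
  cy <- (d[2] - 1) / 2 * voxel_size[2] - R
  x <- (seq_len(d[1]) - 1) * voxel_size[1]
  y <- (seq_len(d[2]) - 1) * voxel_size[2]
  rx <- outer(x - cx, rep(1, d[2]))
  ry <- outer(rep(1, d[1]), y - cy)
  nrm <- sqrt(rx^2 + ry^2)
  nrm[nrm == 0] <- 1
  tx <- ry / nrm; ty <- -rx / nrm
  for (k in seq_len(d[3])) {
    out[, , k, 1] <- tx
    out[, , k, 2] <- ty
  }
  out
}

## orthonormal frame with first column along v
frame_from_direction <- function(v) {
  v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * v) * v
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(v[2] * e2[3] - v[3] * e2[2],
          v[3] * e2[1] - v[1] * e2[3],
          v[1] * e2[2] - v[2] * e2[1])
  cbind(v, e2, e3, deparse.level = 0)
}

#' Generate a synthetic DTI/NODDI phantom
#'
#' Builds all pipeline inputs for the requested scenario with known
#' ground truth: white matter carries prolate tensors aligned with the
#' fibre field at the prescribed FA, grey matter and CSF carry isotropic
#' ones, and the compartment maps satisfy every container invariant
#' (fractions in `[0, 1]` summing to 1, FA in `[0, 1]`, unit fibre
#' vectors).  Mean water diffusivity is 0.7e-9 m^2/s in parenchyma and
#' 3e-9 m^2/s in CSF, typical in-vivo magnitudes; the diffusivity
#' builder renormalises them anyway.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `ced_phantom`: `tensor` ([tensor_volume()]),
#'   `fa`, `noddi`, `mask`, `labels_truth` (integer array with the
#'   generator's tissue partition), `fibres` (unit-vector array), and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  vs <- spec$voxel_size
  nvox <- prod(d)
  lab <- array(2L, d) ## WM by default
  fa_map <- array(spec$fa_wm, d)
  vfw <- array(spec$vf_water, d)
  ecs <- if (length(spec$vf_ecs) == 2L) {
    z <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1)
    array(rep(spec$vf_ecs[1] + z * diff(spec$vf_ecs),
              each = d[1] * d[2]), d)
  } else array(spec$vf_ecs, d)
  fibres <- switch(spec$scenario,
                   uniform_wm_slab = {
                     f <- array(0, c(d, 3))
                     for (q in 1:3) f[, , , q] <- spec$fibre_direction[q]
                     f
                   },
                   curved_bundle = curved_bundle_field(d, vs,
                                                       spec$curvature),
                   three_tissue = {
                     f <- array(0, c(d, 3))
                     f[, , , 1] <- 1
                     f
                   })
  if (spec$scenario == "three_tissue") {
    z3 <- ceiling(d[3] / 3)
    gm_slices <- (z3 + 1):(2 * z3)
    csf_slices <- (2 * z3 + 1):d[3]
    lab[, , gm_slices] <- 1L
    lab[, , csf_slices] <- 3L
    fa_map[, , gm_slices] <- spec$fa_gm
    fa_map[, , csf_slices] <- 0.02
    vfw[, , csf_slices] <- 0.995
    ecs[, , csf_slices] <- 0.997
  }
  if (spec$noise > 0) {
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    fa_map <- array(clip(fa_map + stats::rnorm(nvox, 0, spec$noise),
                         ifelse(lab == 2L, 0.2301, 0),
                         ifelse(lab == 2L, 0.999, 0.2299)), d)
    ecs <- array(clip(ecs + stats::rnorm(nvox, 0, spec$noise),
                      pmax(0.15, vfw + 1e-3), 0.80), d)
    ecs[lab == 3L] <- 0.997
  }
  vf_enc <- ecs - vfw
  vf_inc <- 1 - ecs
  mask <- array(TRUE, d)
  mk <- function(x) scalar_volume(array(x, d), voxel_size = vs,
                                  mask = mask)
  noddi <- noddi_maps(mk(vf_inc), mk(vf_enc), mk(vfw))
  ## tensors: prolate at the map FA, aligned with the fibre field
  lbar <- array(0.7e-9, d)
  lbar[lab == 3L] <- 3e-9
  tens <- array(0, c(d, 6))
  tcache <- new.env()
  for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    for (i in seq_len(d[1])) {
      fa_v <- fa_map[i, j, k]
      key <- format(fa_v, digits = 12)
      tt <- tcache[[key]]
      if (is.null(tt)) {
        tt <- fa_to_eigenratio(fa_v)
        tcache[[key]] <- tt
      }
      l1 <- 3 * lbar[i, j, k] / (1 + 2 * tt)
      lam <- c(l1, l1 * tt, l1 * tt)
      E <- frame_from_direction(fibres[i, j, k, ])
      tens[i, j, k, ] <- tensor_pack(tensor_from_eigen(E, lam))
    }
  out <- list(tensor = tensor_volume(tens, voxel_size = vs,
                                     mask = mask),
              fa = mk(fa_map), noddi = noddi, mask = mask,
              labels_truth = lab, fibres = fibres, spec = spec)
  class(out) <- "ced_phantom"
  out
}

#' @export
print.ced_phantom <- function(x, ...) {
  cat("<ced_phantom>", x$spec$scenario, "on",
      paste(x$spec$shape, collapse = " x "), "grid,",
      paste0(x$spec$voxel_size[1], " mm voxels\n"))
  invisible(x)
}

#' Write a phantom to NIfTI files plus a manifest
#'
#' Writes `fa`, the compartment-fraction maps, the tensor volume and the
#' mask in the dialects the volume readers consume, together with a JSON
#' manifest recording the seed and full specification.
#'
#' @param phantom a [generate_phantom()] result.
#' @param directory existing output directory.
#' @return Named character vector of the written files, invisibly.
#' @export
write_phantom <- function(phantom, directory) {
  stopifnot(inherits(phantom, "ced_phantom"))
  if (!dir.exists(directory))
    stop("directory does not exist: ", directory)
  f <- function(name) file.path(directory, name)
  files <- c(fa = f("fa.nii.gz"), vf_inc = f("vf_inc.nii.gz"),
             vf_enc = f("vf_enc.nii.gz"),
             vf_water = f("vf_water.nii.gz"),
             tensor = f("tensor.nii.gz"), mask = f("mask.nii.gz"),
             manifest = f("manifest.json"))
  write_scalar_volume(phantom$fa, files["fa"])
  write_scalar_volume(phantom$noddi$vf_inc, files["vf_inc"])
  write_scalar_volume(phantom$noddi$vf_enc, files["vf_enc"])
  write_scalar_volume(phantom$noddi$vf_water, files["vf_water"])
  write_tensor_volume(phantom$tensor, files["tensor"])
  mask_vol <- scalar_volume(array(as.numeric(phantom$mask),
                                  dim(phantom$mask)),
                            voxel_size = phantom$spec$voxel_size)
  write_scalar_volume(mask_vol, files["mask"])
  jsonlite::write_json(list(seed = phantom$spec$seed,
                            spec = unclass(phantom$spec),
                            files = as.list(files[names(files) !=
                                                    "manifest"])),
                       files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
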