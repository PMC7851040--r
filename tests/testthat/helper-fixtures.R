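## shared in-code fixtures for the test suite

## homogeneous isotropic tensor volume on a full-grid mask
iso_tensor_volume <- function(n, voxel_size, k_iso) {
  tens <- array(0, c(n, n, n, 6))
  tens[, , , 1] <- k_iso; tens[, , , 3] <- k_iso; tens[, , , 6] <- k_iso
  tensor_volume(tens, voxel_size = voxel_size,
                mask = array(TRUE, c(n, n, n)))
}

## homogeneous diagonal-anisotropic tensor volume
diag_tensor_volume <- function(n, voxel_size, kx, ky, kz,
                               mask = array(TRUE, c(n, n, n))) {
  tens <- array(0, c(n, n, n, 6))
  tens[, , , 1] <- kx; tens[, , , 3] <- ky; tens[, , , 6] <- kz
  tensor_volume(tens, voxel_size = voxel_size, mask = mask)
}

## unit-range scalar volume from an array
svol <- function(a, voxel_size = 1) {
  scalar_volume(a, voxel_size = voxel_size,
                mask = array(TRUE, dim(a)))
}

## random symmetric positive-definite 3x3 matrix
random_spd <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  A %*% t(A) + diag(3) * 0.1
}

## spherical-mask Darcy case used by the radial-pressure oracle
radial_case <- function(n, domain_mm = 40, R_mm = 18, K0 = 1e-14) {
  vs <- domain_mm / n
  ctr <- (n - 1) / 2 * vs
  x <- (seq_len(n) - 1) * vs
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  rr <- sqrt((X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2)
  mask <- rr <= R_mm
  tens <- array(0, c(n, n, n, 6))
  tens[, , , 1] <- K0; tens[, , , 3] <- K0; tens[, , , 6] <- K0
  list(K = tensor_volume(tens, voxel_size = vs, mask = mask),
       catheter = catheter_spec(tip = rep(ctr, 3)),
       rr = rr, mask = mask, R_mm = R_mm, K0 = K0, ctr = ctr, vs = vs)
}

## relative L2 error of the computed pressure against the radial
## point-source closed form, away from the source and outer boundary
radial_pressure_error <- function(n) {
  cs <- radial_case(n)
  sol <- solve_pressure(cs$K, cs$catheter, simulation_config())
  mu <- 1e-3; Q <- cs$catheter$flow_rate
  pex <- Q * mu / (4 * pi * cs$K0) *
    (1 / (cs$rr * 1e-3) - 1 / (cs$R_mm * 1e-3))
  sel <- cs$mask & cs$rr > 4 & cs$rr < 15
  sqrt(mean((sol$pressure$data[sel] - pex[sel])^2)) /
    sqrt(mean(pex[sel]^2))
}

## cache expensive objects across test files within one run
fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

## the microscale sweep used by the law-recovery checks (~40 s)
default_sweep <- function() cached("sweep", microscale_sweep())

## the uniform white-matter slab infusion used by the
## direction-following checks (~1 min)
slab_infusion <- function() cached("slab", {
  ph <- generate_phantom(phantom_spec("uniform_wm_slab",
                                      shape = c(41, 41, 41),
                                      voxel_size = 0.6))
  ctr <- 20 * 0.6
  cath <- catheter_spec(tip = rep(ctr, 3), orientation = c(1, 0, 0))
  cfg <- simulation_config(total_time = 180, dt = 2)
  list(phantom = ph, catheter = cath, config = cfg,
       result = run_case(ph$tensor, ph$fa, ph$noddi, cath, cfg,
                         mode = "dti"))
})
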