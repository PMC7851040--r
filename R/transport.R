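#' Transient advection-diffusion-loss transport of the infused tracer
#'
#' Integrates
#' \deqn{\partial c/\partial t = -\nabla\cdot(v c)
#'       + \nabla\cdot(D \nabla c) - \lambda c + s}
#' on the voxel grid, with `v` the steady Darcy velocity (as face
#' fluxes), a first-order loss rate `lambda`, solute inflow `Q c0` at the
#' catheter voxels, and zero solute flux through the outer mask boundary
#' (the glia-limitans condition: fluid may leave, solute may not).  The
#' scheme is a conservative explicit finite-volume update — first-order
#' upwind advection, central diffusion with harmonic face means (plus
#' explicit central cross terms for full-tensor diffusivity), and an
#' exact exponential factor for the loss term — sub-stepped automatically
#' to satisfy the advective/diffusive stability limit, which makes the
#' update a convex combination of old values and the inlet concentration
#' and hence bounded in `[0, c0]`.
#'
#' @param darcy a [solve_pressure()] result (supplies the face fluxes,
#'   grid, mask and source voxels).
#' @param D a [tensor_volume()] of diffusivities (m^2/s).
#' @param catheter a [catheter_spec()].
#' @param config a [simulation_config()].
#' @param output_times increasing times (s) at which to store
#'   concentration snapshots; defaults to `config$total_time`.
#' @param c_init optional initial concentration array (mol/m^3),
#'   default 0.
#' @return An object of class `ced_transport`: snapshots `conc` (list of
#'   [scalar_volume()], mol/m^3), `times`, a mass-budget data frame
#'   (mol), and the sub-stepping log.
#' @export
solve_transport <- function(darcy, D, catheter, config,
                            output_times = NULL, c_init = NULL) {
  stopifnot(inherits(darcy, "darcy_solution"),
            inherits(D, "tensor_volume"))
  if (is.null(output_times)) output_times <- config$total_time
  output_times <- sort(unique(output_times))
  mask <- darcy$mask
  d <- dim(mask)
  hm <- mm_to_m(darcy$voxel_size)
  areas <- c(hm[2] * hm[3], hm[1] * hm[3], hm[1] * hm[2])
  V <- prod(hm)
  lam <- config$loss_rate
  c0 <- catheter$c0_si
  Q <- catheter$flow_rate
  src <- darcy$source_voxels
  src_w <- attr(src, "weights")
  if (is.null(src_w)) src_w <- rep(1 / nrow(src), nrow(src))
  src_rate <- Q * c0 * src_w ## mol/s per source voxel
  cc <- if (is.null(c_init)) array(0, d) else array(c_init, d)
  cc[!mask] <- 0
  ## interior-face masks, upwind split fluxes and diffusive conductances
  Fpos <- Fneg <- Gd <- intf <- vector("list", 3)
  diag_comp <- c(1L, 3L, 6L)
  out_adv <- array(0, d); diff_sum <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    mP <- slice_axis(mask, ax, 1:(n - 1))
    mN <- slice_axis(mask, ax, 2:n)
    both <- mP & mN
    intf[[ax]] <- both
    Ff <- slice_axis(darcy$faces[[ax]], ax, 2:n) ## interior faces
    Ff[!both] <- 0
    Fpos[[ax]] <- pmax(Ff, 0); Fneg[[ax]] <- pmin(Ff, 0)
    Kdd <- D$data[, , , diag_comp[ax]]
    DP <- slice_axis(Kdd, ax, 1:(n - 1)); DN <- slice_axis(Kdd, ax, 2:n)
    G <- array(0, dim(both))
    pos <- both & DP > 0 & DN > 0
    G[pos] <- areas[ax] * 2 / (1 / DP[pos] + 1 / DN[pos]) / hm[ax]
    Gd[[ax]] <- G
    ## stability bookkeeping
    oa <- array(0, d)
    oa <- assign_axis(oa, ax, 1:(n - 1), Fpos[[ax]])
    oa2 <- array(0, d)
    oa2 <- assign_axis(oa2, ax, 2:n, -Fneg[[ax]])
    out_adv <- out_adv + oa + oa2
    ds <- array(0, d)
    ds <- assign_axis(ds, ax, 1:(n - 1), G)
    ds2 <- array(0, d)
    ds2 <- assign_axis(ds2, ax, 2:n, G)
    diff_sum <- diff_sum + ds + ds2
  }
  has_cross <- max(abs(D$data[, , , c(2L, 4L, 5L)])) > 0
  use_lim <- identical(config$limiter, "vanleer")
  if (use_lim) {
    ## validity of the far-upwind neighbour used by the MUSCL slopes
    Wok <- Eok <- vector("list", 3)
    for (ax in 1:3) {
      n <- d[ax]; nf <- n - 1L
      wk <- array(FALSE, dim(Fpos[[ax]]))
      ek <- array(FALSE, dim(Fpos[[ax]]))
      if (nf >= 2) {
        wk <- assign_axis(wk, ax, 2:nf, slice_axis(mask, ax, 1:(nf - 1)))
        ek <- assign_axis(ek, ax, 1:(nf - 1), slice_axis(mask, ax, 3:n))
      }
      Wok[[ax]] <- wk; Eok[[ax]] <- ek
    }
  }
  rate_max <- max((out_adv + diff_sum)[mask]) / V
  dt_stab <- if (rate_max > 0) config$cfl / rate_max else Inf
  if (use_lim) dt_stab <- dt_stab / 2 ## stricter TVD step bound
  substep_log <- list()
  budget <- data.frame(time = numeric(0), fluid_injected = numeric(0),
                       injected = numeric(0), decayed = numeric(0),
                       mass = numeric(0), residual_rel = numeric(0))
  injected <- decayed <- 0
  mass0 <- sum(cc[mask]) * V
  t_now <- 0
  snapshots <- vector("list", length(output_times))
  mk_vol <- function(a) scalar_volume(a, voxel_size = darcy$voxel_size,
                                      affine = darcy$affine,
                                      mask = mask)
  for (oi in seq_along(output_times)) {
    t_target <- output_times[oi]
    while (t_now < t_target - 1e-12) {
      dt <- min(config$dt, t_target - t_now)
      if (dt > dt_stab) {
        nsub <- ceiling(dt / dt_stab)
        dt <- dt / nsub
        substep_log[[length(substep_log) + 1L]] <-
          sprintf("t = %.3f s: dt reduced to %.4g s (%d sub-steps)",
                  t_now, dt, nsub)
      } else nsub <- 1L
      for (s in seq_len(nsub)) {
        dm <- array(0, d) ## mol/s net into each voxel
        for (ax in 1:3) {
          n <- d[ax]
          cP <- slice_axis(cc, ax, 1:(n - 1))
          cN <- slice_axis(cc, ax, 2:n)
          flow <- Fpos[[ax]] * cP + Fneg[[ax]] * cN ## advective, +ax
          if (use_lim) {
            ## van Leer MUSCL correction towards second order
            nf <- n - 1L
            dc <- cN - cP
            cW <- array(0, dim(dc)); cE <- array(0, dim(dc))
            if (nf >= 2) {
              cW <- assign_axis(cW, ax, 2:nf,
                                slice_axis(cc, ax, 1:(nf - 1)))
              cE <- assign_axis(cE, ax, 1:(nf - 1),
                                slice_axis(cc, ax, 3:n))
            }
            dnz <- ifelse(dc == 0, 1, dc)
            rp <- (cP - cW) / dnz
            rp[!Wok[[ax]] | dc == 0] <- 0
            php <- (rp + abs(rp)) / (1 + abs(rp))
            rn <- (cN - cE) / -dnz
            rn[!Eok[[ax]] | dc == 0] <- 0
            phn <- (rn + abs(rn)) / (1 + abs(rn))
            flow <- flow + Fpos[[ax]] * (0.5 * php * dc) +
              Fneg[[ax]] * (0.5 * phn * (-dc))
          }
          flow <- flow + Gd[[ax]] * (cP - cN)       ## diffusive, +ax
          dm <- assign_axis(dm, ax, 1:(n - 1),
                            slice_axis(dm, ax, 1:(n - 1)) - flow)
          dm <- assign_axis(dm, ax, 2:n,
                            slice_axis(dm, ax, 2:n) + flow)
        }
        if (has_cross) {
          for (ax in 1:3) {
            n <- d[ax]
            Fc <- cross_fluxes_axis(cc, D, mask, ax, hm, areas[ax], 1)
            dm <- assign_axis(dm, ax, 1:(n - 1),
                              slice_axis(dm, ax, 1:(n - 1)) - Fc)
            dm <- assign_axis(dm, ax, 2:n,
                              slice_axis(dm, ax, 2:n) + Fc)
          }
        }
        cc <- cc + dt * dm / V
        cc[src] <- cc[src] + dt * src_rate / V
        injected <- injected + dt * sum(src_rate)
        if (lam > 0) {
          f <- exp(-lam * dt)
          decayed <- decayed + sum(cc[mask]) * V * (1 - f)
          cc <- cc * f
        }
        cc[!mask] <- 0
        t_now <- t_now + dt
      }
    }
    mass <- sum(cc[mask]) * V
    resid <- (mass0 + injected - decayed - mass) /
      max(mass0 + injected, .Machine$double.eps)
    budget <- rbind(budget,
                    data.frame(time = t_target,
                               fluid_injected = Q * t_target,
                               injected = injected, decayed = decayed,
                               mass = mass, residual_rel = resid))
    snapshots[[oi]] <- mk_vol(cc)
  }
  structure(list(conc = snapshots, times = output_times,
                 budget = budget,
                 substeps = unlist(substep_log),
                 dt_stability = dt_stab, c0_si = c0),
            class = "ced_transport")
}

#' @export
print.ced_transport <- function(x, ...) {
  cat("<ced_transport>", length(x$times), "snapshot(s), final t =",
      max(x$times), "s\n")
  b <- x$budget[nrow(x$budget), ]
  cat(sprintf(
    "  injected %.4g mol, decayed %.4g mol, in tissue %.4g mol (residual %.1e)\n",
    b$injected, b$decayed, b$mass, b$residual_rel))
  invisible(x)
}

## internal: quiescent flow field (zero fluxes) for transport oracles
zero_darcy <- function(mask, voxel_size, source = NULL) {
  d <- dim(mask)
  faces <- list(array(0, d + c(1, 0, 0)), array(0, d + c(0, 1, 0)),
                array(0, d + c(0, 0, 1)))
  if (is.null(source))
    source <- matrix(ceiling(d / 2), 1)
  structure(list(pressure = NULL, velocity = array(0, c(d, 3)),
                 faces = faces, source_voxels = source,
                 mass_balance_error = 0, mask = mask,
                 voxel_size = voxel_size, affine = diag(c(voxel_size, 1)),
                 catheter = NULL, mu = 1e-3),
            class = "darcy_solution")
}
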