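## internal: voxels receiving the catheter source (tip-face disk)
source_voxels <- function(K, catheter, mask) {
  d <- dim(K$data)[1:3]
  vol_meta <- list(affine = K$affine)
  ## sample the tip face: centre + two rings, in mm
  axis <- catheter$orientation
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  rad_mm <- catheter$diameter / 2 * 1e3
  ## dense uniform-area sampling of the tip disk; per-voxel weights are
  ## the fraction of samples landing in each voxel, so the volumetric
  ## source converges with the grid
  nring <- 8L
  pts <- catheter$tip
  for (q in seq_len(nring)) {
    rq <- rad_mm * sqrt((q - 0.5) / nring)
    nang <- max(8L, 6L * q)
    ang <- seq(0, 2 * pi, length.out = nang + 1L)[-1L]
    pts <- rbind(pts,
                 t(vapply(ang, function(a)
                   catheter$tip + rq * (cos(a) * e1 + sin(a) * e2),
                   numeric(3))))
  }
  vox <- round(world_to_voxel(vol_meta, pts)) + 1
  keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
    vox[, 2] >= 1 & vox[, 2] <= d[2] &
    vox[, 3] >= 1 & vox[, 3] <= d[3]
  vox <- vox[keep, , drop = FALSE]
  if (nrow(vox) == 0) stop("catheter tip lies outside the volume")
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  counts <- table(key)
  uni <- vox[!duplicated(key), , drop = FALSE]
  w <- as.numeric(counts[paste(uni[, 1], uni[, 2], uni[, 3])])
  inm <- mask[uni]
  if (!any(inm)) stop("catheter tip lies outside the brain mask")
  uni <- uni[inm, , drop = FALSE]
  w <- w[inm]
  structure(uni, weights = w / sum(w))
}

## internal: face-centred cross-term fluxes of -(T_offdiag grad p) A / mu.
## `comp` picks (K12, K13) for x-faces etc.  Returns fluxes on interior
## faces only; p is taken as 0 outside the mask (Dirichlet boundary).
cross_fluxes_axis <- function(p, K, mask, axis, hm, area, mu) {
  d <- dim(p)
  grad_center <- function(f, ax) {
    g <- array(0, d)
    lo <- array(0, d); hi <- array(0, d)
    n <- d[ax]
    idx <- function(r) switch(ax,
                              list(r, TRUE, TRUE),
                              list(TRUE, r, TRUE),
                              list(TRUE, TRUE, r))
    sub <- function(a, r) do.call(`[`, c(list(a), idx(r), list(drop = FALSE)))
    asn <- function(a, r, val) {
      a <- do.call(`[<-`, c(list(a), idx(r), list(val))); a
    }
    hi <- asn(hi, 1:(n - 1), sub(f, 2:n)); hi <- asn(hi, n, 0)
    lo <- asn(lo, 2:n, sub(f, 1:(n - 1))); lo <- asn(lo, 1, 0)
    (hi - lo) / (2 * hm[ax])
  }
  others <- setdiff(1:3, axis)
  comp_of <- function(i, j) { ## component column in the packed tensor
    key <- paste(sort(c(i, j)), collapse = "")
    switch(key, "11" = 1L, "12" = 2L, "22" = 3L, "13" = 4L,
           "23" = 5L, "33" = 6L)
  }
  pm <- p; pm[!mask] <- 0
  n <- d[axis]
  slice <- function(a, r) {
    idx <- switch(axis, list(r, TRUE, TRUE), list(TRUE, r, TRUE),
                  list(TRUE, TRUE, r))
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  total <- 0
  for (ax2 in others) {
    g <- grad_center(pm, ax2)
    Koff <- K$data[, , , comp_of(axis, ax2)]
    gP <- slice(g, 1:(n - 1)); gN <- slice(g, 2:n)
    KP <- slice(Koff, 1:(n - 1)); KN <- slice(Koff, 2:n)
    total <- total - area * 0.5 * (KP + KN) * 0.5 * (gP + gN) / mu
  }
  mP <- slice(mask, 1:(n - 1)); mN <- slice(mask, 2:n)
  total * (mP & mN)
}

#' Steady Darcy pressure and velocity on the voxel grid
#'
#' Finite-volume solution of incompressible Darcy flow
#' \eqn{\nabla\cdot(-(K/\mu)\nabla p) = q} on the in-mask voxels, with
#' the catheter volumetric source `q` (the infusion rate distributed
#' over the tip voxels) and a homogeneous Dirichlet condition `p = 0` on
#' the outer mask surface (the brain surface).  Normal tensor components
#' use two-point fluxes with harmonic face means, which makes the system
#' symmetric positive definite; off-diagonal tensor components are
#' handled by a deferred-correction iteration with central-difference
#' cross gradients (exact single solve for axis-aligned tensor fields).
#' Discrete mass is conserved: total outflow across the mask boundary
#' equals the infusion rate to solver precision.
#'
#' @param K a [tensor_volume()] of permeabilities (m^2), SPD in-mask.
#' @param catheter a [catheter_spec()].
#' @param config a [simulation_config()] (viscosity, iteration control).
#' @param mask optional logical array overriding `K$mask`.
#' @return An object of class `darcy_solution`: pressure
#'   ([scalar_volume()], Pa), cell-centred superficial velocity (array
#'   `nx x ny x nz x 3`, m/s), face volume fluxes (m^3/s), the source
#'   voxel index matrix, and the relative mass-balance error.
#' @export
solve_pressure <- function(K, catheter, config = simulation_config(),
                           mask = NULL) {
  stopifnot(inherits(K, "tensor_volume"),
            inherits(catheter, "catheter_spec"))
  if (is.null(mask)) mask <- K$mask
  d <- dim(K$data)[1:3]
  if (!any(mask)) stop("empty mask: singular system")
  hm <- mm_to_m(K$voxel_size)
  areas <- c(hm[2] * hm[3], hm[1] * hm[3], hm[1] * hm[2])
  mu <- config$mu
  nm <- sum(mask)
  idm <- array(0L, d); idm[mask] <- seq_len(nm)
  diag_comp <- c(1L, 3L, 6L)
  rows <- list(); cols <- list(); vals <- list()
  diag_acc <- numeric(nm)
  bnd <- list() ## boundary-face transmissibilities per axis/side
  Tint <- list()
  for (ax in 1:3) {
    n <- d[ax]
    Kdd <- K$data[, , , diag_comp[ax]]
    if (any(Kdd[mask] <= 0)) stop("K must be positive definite in-mask")
    sl <- function(a, r) {
      idx <- switch(ax, list(r, TRUE, TRUE), list(TRUE, r, TRUE),
                    list(TRUE, TRUE, r))
      do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    mP <- sl(mask, 1:(n - 1)); mN <- sl(mask, 2:n)
    both <- mP & mN
    KP <- sl(Kdd, 1:(n - 1)); KN <- sl(Kdd, 2:n)
    Tf <- array(0, dim(both))
    Tf[both] <- areas[ax] * 2 /
      (1 / KP[both] + 1 / KN[both]) / hm[ax]
    Tint[[ax]] <- Tf
    iP <- sl(idm, 1:(n - 1))[both]; iN <- sl(idm, 2:n)[both]
    tv <- Tf[both] / mu
    rows[[length(rows) + 1L]] <- iP; cols[[length(cols) + 1L]] <- iN
    vals[[length(vals) + 1L]] <- -tv
    rows[[length(rows) + 1L]] <- iN; cols[[length(cols) + 1L]] <- iP
    vals[[length(vals) + 1L]] <- -tv
    diag_acc[iP] <- diag_acc[iP] + tv
    diag_acc[iN] <- diag_acc[iN] + tv
    ## boundary faces: first/last slice, or neighbour outside mask
    lowb <- mask & !shift_in(mask, ax, +1L) ## no in-mask neighbour below
    highb <- mask & !shift_in(mask, ax, -1L)
    Tb_low <- areas[ax] * Kdd / (hm[ax] / 2)
    ib <- idm[lowb]
    diag_acc[ib] <- diag_acc[ib] + Tb_low[lowb] / mu
    ib <- idm[highb]
    diag_acc[ib] <- diag_acc[ib] + Tb_low[highb] / mu
    bnd[[ax]] <- list(low = lowb, high = highb, Tb = Tb_low)
  }
  rows[[length(rows) + 1L]] <- seq_len(nm)
  cols[[length(cols) + 1L]] <- seq_len(nm)
  vals[[length(vals) + 1L]] <- diag_acc
  M <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(nm, nm))
  src <- source_voxels(K, catheter, mask)
  rhs <- numeric(nm)
  rhs[idm[src]] <- catheter$flow_rate * attr(src, "weights")
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  pv <- as.numeric(Matrix::solve(ch, rhs))
  p <- array(0, d); p[mask] <- pv
  has_cross <- max(abs(K$data[, , , c(2L, 4L, 5L)])) > 0
  cross <- vector("list", 3)
  if (has_cross) {
    for (it in seq_len(config$max_cross_iter)) {
      corr <- numeric(nm)
      for (ax in 1:3) {
        Fc <- cross_fluxes_axis(p, K, mask, ax, hm, areas[ax], mu)
        cross[[ax]] <- Fc
        n <- d[ax]
        iP <- slice_axis(idm, ax, 1:(n - 1)); iN <- slice_axis(idm, ax,
                                                               2:n)
        sel <- iP > 0 & iN > 0
        corr[iP[sel]] <- corr[iP[sel]] + Fc[sel]
        corr[iN[sel]] <- corr[iN[sel]] - Fc[sel]
      }
      pv_new <- as.numeric(Matrix::solve(ch, rhs - corr))
      delta <- max(abs(pv_new - pv)) / max(max(abs(pv_new)),
                                           .Machine$double.eps)
      pv <- pv_new
      p <- array(0, d); p[mask] <- pv
      if (delta < config$cross_tol) break
    }
    if (delta >= config$cross_tol)
      warning("deferred-correction iteration stopped at relative ",
              "change ", format(delta))
  }
  ## face fluxes (positive along +axis), including mask-boundary faces
  faces <- vector("list", 3)
  outflow <- 0
  for (ax in 1:3) {
    n <- d[ax]
    Ff <- array(0, dim(p) + c(ax == 1, ax == 2, ax == 3))
    pP <- slice_axis(p, ax, 1:(n - 1)); pN <- slice_axis(p, ax, 2:n)
    Fint <- Tint[[ax]] * (pP - pN) / mu
    if (has_cross && !is.null(cross[[ax]]))
      Fint <- Fint + cross[[ax]]
    ## place interior faces at positions 2..n along axis
    Ff <- assign_axis(Ff, ax, 2:n, Fint)
    ## boundary faces
    b <- bnd[[ax]]
    Tb <- b$Tb
    lowF <- array(0, d); lowF[b$low] <- -Tb[b$low] * p[b$low] / mu
    highF <- array(0, d); highF[b$high] <- Tb[b$high] * p[b$high] / mu
    ## low boundary face of voxel at slice r sits at face position r
    for (r in seq_len(n)) {
      lsl <- slice_axis(lowF, ax, r)
      if (any(lsl != 0))
        Ff <- assign_axis(Ff, ax, r, slice_axis(Ff, ax, r) + lsl)
      hsl <- slice_axis(highF, ax, r)
      if (any(hsl != 0))
        Ff <- assign_axis(Ff, ax, r + 1L,
                          slice_axis(Ff, ax, r + 1L) + hsl)
    }
    outflow <- outflow + sum(highF) - sum(lowF)
    faces[[ax]] <- Ff
  }
  mass_err <- abs(outflow - catheter$flow_rate) / catheter$flow_rate
  v <- array(0, c(d, 3))
  for (ax in 1:3) {
    n <- d[ax]
    Ff <- faces[[ax]]
    vc <- (slice_axis(Ff, ax, 1:n) + slice_axis(Ff, ax, 2:(n + 1))) /
      (2 * areas[ax])
    v[, , , ax] <- vc * mask
  }
  structure(list(pressure = scalar_volume(p,
                                          voxel_size = K$voxel_size,
                                          affine = K$affine,
                                          mask = mask),
                 velocity = v, faces = faces, source_voxels = src,
                 mass_balance_error = mass_err, mask = mask,
                 voxel_size = K$voxel_size, affine = K$affine,
                 catheter = catheter, mu = mu),
            class = "darcy_solution")
}

#' @export
print.darcy_solution <- function(x, ...) {
  cat("<darcy_solution>",
      paste(dim(x$pressure$data), collapse = " x "), "grid\n")
  cat(sprintf("  max pressure %.4g Pa; mass balance error %.2e\n",
              max(x$pressure$data), x$mass_balance_error))
  invisible(x)
}

## ---- small axis-slicing helpers ---------------------------------------

slice_axis <- function(a, ax, r) {
  idx <- switch(ax, list(r, TRUE, TRUE), list(TRUE, r, TRUE),
                list(TRUE, TRUE, r))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

assign_axis <- function(a, ax, r, val) {
  idx <- switch(ax, list(r, TRUE, TRUE), list(TRUE, r, TRUE),
                list(TRUE, TRUE, r))
  do.call(`[<-`, c(list(a), idx, list(val)))
}

## logical array shifted so element P reports its neighbour at P -/+ 1
## along `ax` (FALSE where the neighbour falls outside the domain)
shift_in <- function(mask, ax, dir) {
  d <- dim(mask)
  out <- array(FALSE, d)
  n <- d[ax]
  if (dir > 0) ## neighbour at index - 1
    out <- assign_axis(out, ax, 2:n, slice_axis(mask, ax, 1:(n - 1)))
  else
    out <- assign_axis(out, ax, 1:(n - 1), slice_axis(mask, ax, 2:n))
  out
}
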