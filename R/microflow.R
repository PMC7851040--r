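#' Axial creeping flow through the fibre lattice
#'
#' Fully developed Stokes flow parallel to aligned fibres reduces exactly
#' to a 2-D Poisson problem for the axial velocity `w` on the fluid part
#' of the periodic cell cross-section,
#' \deqn{-\mu \nabla^2 w = \Delta p / L,}
#' with no-slip (`w = 0`) on the fibre walls and periodic lateral
#' conditions.  The circular walls are represented with a Shortley–Weller
#' stencil (exact wall distances along grid lines), which makes the
#' scheme second-order accurate and essentially grid-converged at the
#' default resolution.  The superficial mean velocity averages `w` over
#' the full cell cross-section (fluid and solid).
#'
#' @param cell a [build_unit_cell()].
#' @param dp applied pressure difference (Pa); 5 Pa keeps the flow
#'   firmly in the creeping regime.
#' @param L domain length along the flow (m); only the gradient
#'   `dp / L` matters for fully developed flow.
#' @param mu dynamic viscosity (Pa s).  Permeability from Darcy's law is
#'   independent of `mu` in creeping flow.
#' @return An object of class `flow_solution` with fields `dp`, `L`,
#'   `mu`, `v_bar` (superficial mean velocity, m/s), the velocity field
#'   and grid metadata.
#' @export
solve_axial_flow <- function(cell, dp = 5, L = 0.15e-6, mu = 1e-3) {
  stopifnot(inherits(cell, "unit_cell"), dp != 0, L > 0, mu > 0)
  G <- dp / L
  a <- cell$spacing; H <- sqrt(3) * a
  nx <- cell$resolution; ny <- max(4L, round(sqrt(3) * nx))
  hx <- a / nx; hy <- H / ny
  xs <- (seq_len(nx) - 0.5) * hx; ys <- (seq_len(ny) - 0.5) * hy
  centres <- unit_cell_centres(a, H)
  solid <- unit_cell_solid(cell, xs, ys, centres)
  fluid <- !solid
  if (!any(fluid)) stop("no fluid nodes at this resolution")
  idx <- matrix(0L, nx, ny); idx[fluid] <- seq_len(sum(fluid))
  n <- sum(fluid)
  r <- cell$r
  ## fraction of a grid arm from a node to the nearest wall crossing
  theta_dir <- function(x0, y0, dx, dy, h) {
    s <- rep(Inf, length(x0))
    for (k in seq_len(nrow(centres))) {
      cx <- centres[k, 1]; cy <- centres[k, 2]
      if (dx != 0) { perp <- y0 - cy; along0 <- (cx - x0) * sign(dx) }
      else { perp <- x0 - cx; along0 <- (cy - y0) * sign(dy) }
      disc <- r^2 - perp^2
      ok <- disc > 0
      sq <- sqrt(pmax(disc, 0))
      for (root in c(-1, 1)) {
        cand <- along0 + root * sq
        good <- ok & cand > 1e-12 * h
        s[good] <- pmin(s[good], cand[good])
      }
    }
    pmin(pmax(s / h, 1e-6), 1)
  }
  ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
  fi <- which(as.vector(fluid))
  px <- rep(xs, ny)[fi]; py <- rep(ys, each = nx)[fi]
  wrap <- function(i, nmax) ((i - 1) %% nmax) + 1
  nbr <- function(di, dj) idx[cbind(wrap(ii[fi] + di, nx),
                                    wrap(jj[fi] + dj, ny))]
  nE <- nbr(1, 0); nW <- nbr(-1, 0); nN <- nbr(0, 1); nS <- nbr(0, -1)
  thE <- ifelse(nE > 0, 1, theta_dir(px, py, 1, 0, hx))
  thW <- ifelse(nW > 0, 1, theta_dir(px, py, -1, 0, hx))
  thN <- ifelse(nN > 0, 1, theta_dir(px, py, 0, 1, hy))
  thS <- ifelse(nS > 0, 1, theta_dir(px, py, 0, -1, hy))
  me <- idx[fi]
  rows <- me; cols <- me
  vals <- mu * 2 * (1 / (hx^2 * thE * thW) + 1 / (hy^2 * thN * thS))
  link <- function(sel, nb, th, thopp, h) {
    rows <<- c(rows, me[sel]); cols <<- c(cols, nb[sel])
    vals <<- c(vals, -mu * 2 / (h^2 * th[sel] * (th + thopp)[sel]))
  }
  link(nE > 0, nE, thE, thW, hx)
  link(nW > 0, nW, thW, thE, hx)
  link(nN > 0, nN, thN, thS, hy)
  link(nS > 0, nS, thS, thN, hy)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  w <- as.numeric(Matrix::solve(A, rep(G, n)))
  if (any(!is.finite(w)))
    stop("axial flow solve did not converge (non-finite solution)")
  wf <- matrix(0, nx, ny); wf[fluid] <- w
  v_bar <- sum(w) * hx * hy / (a * H)
  structure(list(dp = dp, L = L, mu = mu, v_bar = v_bar,
                 velocity = list(w = wf), fluid = fluid,
                 h = c(hx, hy), cell = cell, direction = "axial"),
            class = "flow_solution")
}

#' Transverse creeping flow through the fibre lattice
#'
#' Solves the 2-D Stokes equations for pressure-driven flow perpendicular
#' to the fibres on one periodic cell, using a staggered
#' (marker-and-cell) finite-difference discretization: velocity unknowns
#' on cell faces, pressures at cell centres, no-slip on fibre walls, and
#' the applied mean pressure gradient `dp / L` entering as a uniform body
#' force (the periodic-cell equivalent of an inlet/outlet pressure
#' difference, with no entrance effects by construction).  The lattice's
#' mirror symmetry about the fibre rows is exploited to solve on half a
#' cell with symmetry conditions.
#'
#' @inheritParams solve_axial_flow
#' @return A `flow_solution`; `v_bar` is the superficial mean velocity
#'   along the pressure-gradient direction.
#' @export
solve_transverse_flow <- function(cell, dp = 5, L = 0.15e-6, mu = 1e-3) {
  stopifnot(inherits(cell, "unit_cell"), dp != 0, L > 0, mu > 0)
  G <- dp / L
  a <- cell$spacing; H2 <- sqrt(3) * a / 2
  nx <- cell$resolution
  ny <- max(4L, round(nx * sqrt(3) / 2))
  hx <- a / nx; hy <- H2 / ny
  centres <- rbind(c(0, 0), c(a, 0), c(a / 2, H2), c(-a / 2, H2),
                   c(3 * a / 2, H2))
  xs <- (seq_len(nx) - 0.5) * hx; ys <- (seq_len(ny) - 0.5) * hy
  solid <- unit_cell_solid(cell, xs, ys, centres)
  fluid <- !solid
  if (!any(fluid)) stop("no fluid cells at this resolution")
  wrap <- function(i) ((i - 1) %% nx) + 1
  uact <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) uact[i, ] <- fluid[wrap(i - 1), ] & fluid[i, ]
  vact <- matrix(FALSE, nx, ny - 1)
  for (j in seq_len(ny - 1)) vact[, j] <- fluid[, j] & fluid[, j + 1]
  iu <- matrix(0L, nx, ny); iu[uact] <- seq_len(sum(uact))
  iv <- matrix(0L, nx, ny - 1)
  iv[vact] <- sum(uact) + seq_len(sum(vact))
  ip <- matrix(0L, nx, ny)
  ip[fluid] <- sum(uact) + sum(vact) + seq_len(sum(fluid))
  nun <- sum(uact) + sum(vact) + sum(fluid)
  rows <- vector("list", 0); cols <- vector("list", 0)
  vals <- vector("list", 0)
  add <- function(r_, c_, v_) {
    rows[[length(rows) + 1L]] <<- r_
    cols[[length(cols) + 1L]] <<- c_
    vals[[length(vals) + 1L]] <<- rep_len(v_, length(r_))
  }
  rhs <- numeric(nun)
  uw <- which(uact, arr.ind = TRUE)
  for (q in seq_len(nrow(uw))) {
    i <- uw[q, 1]; j <- uw[q, 2]; me <- iu[i, j]
    diag_v <- 0
    for (di in c(-1, 1)) {
      nbx <- iu[wrap(i + di), j]
      diag_v <- diag_v + mu / hx^2
      if (nbx > 0) add(me, nbx, -mu / hx^2)
    }
    for (dj in c(-1, 1)) {
      jn <- j + dj
      if (jn >= 1 && jn <= ny) {
        ## wall (inactive neighbour face) contributes u = 0 at that face
        nby <- iu[i, jn]
        diag_v <- diag_v + mu / hy^2
        if (nby > 0) add(me, nby, -mu / hy^2)
      }
      ## beyond a symmetry plane: du/dy = 0, ghost equals me, no term
    }
    add(me, me, diag_v)
    pE <- ip[i, j]; pW <- ip[wrap(i - 1), j]
    if (pE > 0) add(me, pE, 1 / hx)
    if (pW > 0) add(me, pW, -1 / hx)
    rhs[me] <- G
  }
  vw <- which(vact, arr.ind = TRUE)
  for (q in seq_len(nrow(vw))) {
    i <- vw[q, 1]; j <- vw[q, 2]; me <- iv[i, j]
    diag_v <- 0
    for (di in c(-1, 1)) {
      nbx <- iv[wrap(i + di), j]
      diag_v <- diag_v + mu / hx^2
      if (nbx > 0) add(me, nbx, -mu / hx^2)
    }
    for (dj in c(-1, 1)) {
      jn <- j + dj
      diag_v <- diag_v + mu / hy^2
      if (jn >= 1 && jn <= ny - 1) {
        nby <- iv[i, jn]
        if (nby > 0) add(me, nby, -mu / hy^2)
      } ## v = 0 on the symmetry planes
    }
    add(me, me, diag_v)
    pN <- ip[i, j + 1]; pS <- ip[i, j]
    if (pN > 0) add(me, pN, 1 / hy)
    if (pS > 0) add(me, pS, -1 / hy)
  }
  fw <- which(fluid, arr.ind = TRUE)
  pinned <- FALSE
  for (q in seq_len(nrow(fw))) {
    i <- fw[q, 1]; j <- fw[q, 2]; me <- ip[i, j]
    if (!pinned) { add(me, me, 1); pinned <- TRUE; next }
    uE <- iu[wrap(i + 1), j]; uW <- iu[i, j]
    if (uE > 0) add(me, uE, 1 / hx)
    if (uW > 0) add(me, uW, -1 / hx)
    vN <- if (j <= ny - 1) iv[i, j] else 0L
    vS <- if (j - 1 >= 1) iv[i, j - 1] else 0L
    if (vN > 0) add(me, vN, 1 / hy)
    if (vS > 0) add(me, vS, -1 / hy)
  }
  A <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(nun, nun))
  sol <- as.numeric(Matrix::solve(A, rhs))
  if (any(!is.finite(sol)))
    stop("transverse Stokes solve did not converge (non-finite solution)")
  nu <- sum(uact)
  ufield <- matrix(0, nx, ny); ufield[uact] <- sol[seq_len(nu)]
  vfield <- matrix(0, nx, ny - 1)
  vfield[vact] <- sol[nu + seq_len(sum(vact))]
  v_bar <- sum(ufield) / (nx * ny)
  structure(list(dp = dp, L = L, mu = mu, v_bar = v_bar,
                 velocity = list(u = ufield, v = vfield), fluid = fluid,
                 h = c(hx, hy), cell = cell, direction = "transverse"),
            class = "flow_solution")
}

#' Plane-Poiseuille channel flow (solver oracle)
#'
#' Degenerate geometry replacing the fibre lattice by a parallel-plate
#' channel of gap `h`, solved with the same pressure-gradient-driven
#' formulation and Shortley–Weller wall treatment as
#' [solve_axial_flow()].  Its permeability has the exact closed form
#' `h^2 / 12`, which makes it an independent check of the axial solver
#' machinery.
#'
#' @param gap channel gap (m).
#' @param n number of grid cells across the gap.
#' @inheritParams solve_axial_flow
#' @return A `flow_solution`.
#' @export
solve_channel_flow <- function(gap, dp = 5, L = 0.15e-6, mu = 1e-3,
                               n = 64L) {
  stopifnot(gap > 0, dp != 0, L > 0, mu > 0)
  G <- dp / L
  h <- gap / n
  ## cell-centred nodes; walls half a cell beyond the first/last node
  main <- rep(2, n); main[1] <- main[n] <- 2 / (1 * 0.5) ## S-W theta = 1/2
  off <- rep(-1, n - 1); off[1] <- off[n - 1] <- -2 / (1 * 1.5)
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(off, main, off))
  w <- as.numeric(Matrix::solve(A * mu / h^2, rep(G, n)))
  structure(list(dp = dp, L = L, mu = mu, v_bar = mean(w),
                 velocity = list(w = matrix(w, n, 1)),
                 fluid = matrix(TRUE, n, 1), h = c(h, h), cell = NULL,
                 direction = "channel"),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> %s flow: dp = %g Pa, L = %.3g m, v_bar = %.4g m/s\n",
    x$direction, x$dp, x$L, x$v_bar))
  cat(sprintf("  permeability (Darcy): %.4g m^2\n",
              permeability_from_darcy(x)))
  invisible(x)
}

#' Permeability from Darcy's law
#'
#' \eqn{k = \bar v \mu L / \Delta p} for a creeping-flow solution; the
#' result is independent of both the applied pressure difference and the
#' viscosity.
#'
#' @param sol a `flow_solution`.
#' @return Permeability in m^2.
#' @export
permeability_from_darcy <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  sol$v_bar * sol$mu * sol$L / sol$dp
}
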