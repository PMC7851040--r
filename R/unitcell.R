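#' Triangular fibre-lattice unit cell
#'
#' Builds the periodic representative volume element of an aligned axon
#' bundle: parallel cylinders of radius `r` on a triangular lattice with
#' centre-to-centre spacing `a`.  The extracellular (fluid) fraction of
#' the lattice is \eqn{VF_{ECS} = 1 - 2\pi r^2 / (\sqrt{3} a^2)}, so the
#' spacing realising a target fraction is
#' \deqn{a = r\sqrt{\frac{2\pi}{\sqrt{3}\,(1 - VF_{ECS})}}.}
#' The rectangular periodic cell is `a` by `sqrt(3) a` and contains two
#' fibres.  Feasibility requires `a > 2r`, i.e.
#' `vf_ecs > 1 - pi/(2 sqrt(3)) ~ 0.0931` (touching fibres).
#'
#' @param vf_ecs target extracellular volume fraction.
#' @param r fibre radius (m).
#' @param resolution number of grid cells across the spacing `a` used by
#'   the flow solvers.
#' @return An object of class `unit_cell`.
#' @export
build_unit_cell <- function(vf_ecs, r = tissue_constants()$r_axon,
                            resolution = 128L) {
  vf_min <- 1 - pi / (2 * sqrt(3))
  if (vf_ecs <= vf_min || vf_ecs >= 1)
    stop(sprintf("infeasible vf_ecs = %g; must lie in (%.4f, 1)",
                 vf_ecs, vf_min))
  if (r <= 0) stop("fibre radius must be positive")
  a <- r * sqrt(2 * pi / (sqrt(3) * (1 - vf_ecs)))
  realized <- 1 - 2 * pi * r^2 / (sqrt(3) * a^2)
  structure(list(r = r, spacing = a, vf_ecs_target = vf_ecs,
                 vf_ecs = realized, lattice = "triangular",
                 resolution = as.integer(resolution)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> triangular lattice: r = %.3g m, a = %.3g m, VF_ECS = %.4f\n",
    x$r, x$spacing, x$vf_ecs))
  invisible(x)
}

## fibre centres whose disks can intersect the rectangle [0,a]x[0,H]
unit_cell_centres <- function(a, H) {
  rbind(c(0, 0), c(a, 0), c(0, H), c(a, H), c(a / 2, H / 2),
        c(-a / 2, H / 2), c(3 * a / 2, H / 2), c(a / 2, -H / 2),
        c(a / 2, 3 * H / 2))
}

## solid indicator on grid of cell/node centres
unit_cell_solid <- function(cell, xs, ys, centres) {
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  solid <- matrix(FALSE, length(xs), length(ys))
  for (k in seq_len(nrow(centres)))
    solid <- solid | ((X - centres[k, 1])^2 +
                        (Y - centres[k, 2])^2 <= cell$r^2)
  solid
}

#' Discretized extracellular fraction of a unit cell
#'
#' The fluid fraction realised by the solver grid at the cell's
#' resolution; used in the resolution-adequacy checks.
#'
#' @param cell a [build_unit_cell()].
#' @return Fluid area fraction of the discretized cell.
#' @export
discretized_vf_ecs <- function(cell) {
  a <- cell$spacing; H <- sqrt(3) * a
  nx <- cell$resolution; ny <- max(4L, round(sqrt(3) * nx))
  xs <- (seq_len(nx) - 0.5) * (a / nx)
  ys <- (seq_len(ny) - 0.5) * (H / ny)
  solid <- unit_cell_solid(cell, xs, ys, unit_cell_centres(a, H))
  1 - sum(solid) / length(solid)
}
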