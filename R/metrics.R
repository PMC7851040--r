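#' Thresholded infusion region
#'
#' The infusion volume is the set of voxels whose concentration strictly
#' exceeds `c_min = c_min_fraction * c0` (default 2.5% of the inlet
#' concentration).  An empty region is allowed.
#'
#' @param c a [scalar_volume()] of concentrations.
#' @param c0 reference (inlet) concentration, same units as `c`.
#' @param c_min_fraction threshold fraction of `c0`.
#' @param subvoxel refinement factor for the additional
#'   `volume_subvoxel` estimate: the concentration field is trilinearly
#'   interpolated onto a `subvoxel`-times finer lattice before
#'   thresholding, which removes most of the O(h) surface-quantisation
#'   bias of voxel counting (used by grid-convergence studies).  Set to
#'   `1` to skip.
#' @return An object of class `infusion_region`: voxel index matrix,
#'   world voxel-centre coordinates (mm), voxel count `n`, total
#'   `volume` (mm^3, voxel counting) and `volume_subvoxel` (mm^3,
#'   interpolated estimate).
#' @export
infusion_region <- function(c, c0, c_min_fraction = 0.025,
                            subvoxel = 4L) {
  stopifnot(inherits(c, "scalar_volume"), c0 > 0)
  thr <- c_min_fraction * c0
  sel <- c$mask & c$data > thr
  vox <- which(sel, arr.ind = TRUE)
  coords <- if (nrow(vox) > 0) voxel_to_world(c, vox - 1)
  else matrix(numeric(0), 0, 3)
  vol_sub <- if (subvoxel > 1L)
    subvoxel_volume(c$data, c$voxel_size, thr, as.integer(subvoxel))
  else nrow(vox) * prod(c$voxel_size)
  structure(list(voxels = vox, coords = coords, n = nrow(vox),
                 volume = nrow(vox) * prod(c$voxel_size),
                 volume_subvoxel = vol_sub,
                 voxel_size = c$voxel_size, threshold = thr,
                 values = c$data[sel]),
            class = "infusion_region")
}

## fractional threshold volume on a trilinearly refined lattice
subvoxel_volume <- function(cc, voxel_size, thr, m) {
  d <- dim(cc)
  lin_axis <- function(a, ax, q) {
    n <- dim(a)[ax]
    if (n == 1) return(slice_axis(a, ax, rep(1L, length(q))))
    i0 <- pmin(pmax(floor(q), 0), n - 2)
    fr <- q - i0
    lo <- slice_axis(a, ax, i0 + 1)
    hi <- slice_axis(a, ax, i0 + 2)
    frA <- array(0, dim(lo))
    if (ax == 1) frA[] <- fr
    else if (ax == 2) frA[] <- rep(fr, each = dim(a)[1])
    else frA[] <- rep(fr, each = dim(a)[1] * dim(a)[2])
    lo * (1 - frA) + hi * frA
  }
  offs <- (seq_len(m) - 0.5) / m - 0.5
  qs <- function(n) as.vector(outer(offs, 0:(n - 1), `+`))
  a <- lin_axis(cc, 1, qs(d[1]))
  a <- lin_axis(a, 2, qs(d[2]))
  a <- lin_axis(a, 3, qs(d[3]))
  sum(a > thr) * prod(voxel_size / m)
}

#' @export
print.infusion_region <- function(x, ...) {
  cat(sprintf("<infusion_region> %d voxels, %.4g mm^3 (c > %.4g)\n",
              x$n, x$volume, x$threshold))
  invisible(x)
}

#' Root-mean-square concentration difference between two models
#'
#' \deqn{RMSD = \frac{1}{c_0}\sqrt{\frac{1}{V_A \cup V_B}
#'       \sum_i V_i (c_{A,i} - c_{B,i})^2},}
#' where the sum runs over the union of the two thresholded infusion
#' regions and \eqn{V_i} is the per-voxel volume (kept explicitly even
#' though it cancels on a uniform grid).  Returns a fraction of `c0`;
#' 0 when both regions are empty.  Symmetric in its arguments and
#' invariant under a common rescaling of `cA`, `cB` and `c0`.
#'
#' @param cA,cB concentration [scalar_volume()]s on one grid.
#' @param c0 inlet concentration (same units).
#' @param c_min_fraction threshold defining the infusion regions.
#' @return RMSD as a fraction of `c0`.
#' @export
rmsd <- function(cA, cB, c0, c_min_fraction = 0.025) {
  stopifnot(inherits(cA, "scalar_volume"),
            inherits(cB, "scalar_volume"))
  stop_if_grid_mismatch(cA, cB)
  thr <- c_min_fraction * c0
  union_sel <- (cA$mask & cA$data > thr) | (cB$mask & cB$data > thr)
  if (!any(union_sel)) return(0)
  Vi <- prod(cA$voxel_size)
  num <- sum(Vi * (cA$data[union_sel] - cB$data[union_sel])^2)
  den <- sum(rep(Vi, sum(union_sel)))
  sqrt(num / den) / c0
}

#' Principal direction of an infusion region
#'
#' First principal axis of the (unweighted) voxel-centre coordinates of
#' the region, computed by PCA; concentrations do not weight the
#' coordinates by default.  The sign is normalised (first nonzero
#' component positive) since a principal axis is defined up to sign.
#' A degenerate leading eigenvalue pair (spherical region) is flagged
#' with attribute `degenerate`.
#'
#' @param region an [infusion_region()] with at least 2 voxels.
#' @param weighted if `TRUE`, weight coordinates by concentration
#'   (off by default).
#' @return Unit length-3 vector.
#' @export
principal_direction <- function(region, weighted = FALSE) {
  stopifnot(inherits(region, "infusion_region"))
  if (region$n < 2) stop("direction undefined for region with < 2 voxels")
  X <- region$coords
  if (weighted) {
    w <- region$values / sum(region$values)
    mu <- colSums(X * w)
    Xc <- sweep(X, 2, mu) * sqrt(w * region$n)
  } else Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 3)
  dvec <- sv$v[, 1]
  nz <- which(abs(dvec) > 1e-12)[1]
  if (!is.na(nz) && dvec[nz] < 0) dvec <- -dvec
  degen <- length(sv$d) >= 2 &&
    (sv$d[1] - sv$d[2]) <= 1e-8 * max(sv$d[1], .Machine$double.eps)
  attr(dvec, "degenerate") <- degen
  dvec
}

#' Angle between two principal axes
#'
#' Axis (not vector) comparison: `acos(|d1 . d2|)` in degrees, in
#' `[0, 90]`; antiparallel directions give 0.
#'
#' @param d1,d2 direction vectors (normalised internally).
#' @return Angle in degrees.
#' @export
angle_between <- function(d1, d2) {
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  acos(pmin(abs(sum(d1 * d2)), 1)) * 180 / pi
}

#' Linear penetration length along a direction
#'
#' Extent of the region's voxel-centre projections onto `direction`
#' (max minus min) plus one voxel size, so that a single-voxel region
#' has length one voxel rather than zero.  The alternative tip-anchored
#' definition (distance from the catheter tip to the farthest voxel) is
#' available via `from`.
#'
#' @param region an [infusion_region()].
#' @param direction unit projection direction.
#' @param from optional tip coordinates (mm); when given, the length is
#'   `max projection distance from the tip` instead of the extent.
#' @return Length in mm (0 for an empty region).
#' @export
penetration_length <- function(region, direction, from = NULL) {
  stopifnot(inherits(region, "infusion_region"))
  if (region$n == 0) return(0)
  direction <- direction / sqrt(sum(direction^2))
  pr <- as.numeric(region$coords %*% direction)
  if (!is.null(from))
    return(max(abs(pr - sum(from * direction))))
  diff(range(pr)) + mean(region$voxel_size)
}

#' Overlap fraction of two infusion regions
#'
#' Jaccard overlap `|A intersect B| / |A union B|` of the voxel sets,
#' in percent.  The intersection-over-smaller-volume variant is also
#' returned as an attribute, since either convention appears in the
#' infusion-modelling literature.
#'
#' @param regionA,regionB [infusion_region()]s on one grid.
#' @return Percentage in `[0, 100]`, with attribute `over_min`.
#' @export
overlap_fraction <- function(regionA, regionB) {
  stopifnot(inherits(regionA, "infusion_region"),
            inherits(regionB, "infusion_region"))
  key <- function(v) paste(v[, 1], v[, 2], v[, 3])
  A <- key(regionA$voxels); B <- key(regionB$voxels)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  out <- if (uni == 0) 100 else 100 * inter / uni
  attr(out, "over_min") <- if (min(length(A), length(B)) == 0) 100
  else 100 * inter / min(length(A), length(B))
  out
}

#' t tests over the nine-orientation metric samples
#'
#' Standard t statistics with `n - 1` degrees of freedom for the
#' per-orientation metric values: a one-sided one-sample test of
#' `mean > 0` (used for the angular difference) or a two-sided paired
#' test (used for penetration lengths).  Normality is assumed, not
#' re-tested.  Degenerate inputs: a one-sample test with zero variance
#' is an error; a paired test on identical pairs returns statistic 0
#' with p = 1 by convention.
#'
#' @param values numeric vector (one-sample) or its first member
#'   (paired).
#' @param values2 second member of the pairs (paired test only).
#' @param test `"one_sample_one_sided"` or `"paired_two_sided"`.
#' @return List with `statistic`, `p_value`, `df`, `mean`.
#' @export
orientation_stats <- function(values,
                              test = c("one_sample_one_sided",
                                       "paired_two_sided"),
                              values2 = NULL) {
  test <- match.arg(test)
  if (test == "paired_two_sided") {
    if (is.null(values2)) stop("paired test needs values2")
    stopifnot(length(values) == length(values2))
    dif <- values - values2
    if (all(dif == 0))
      return(list(statistic = 0, p_value = 1,
                  df = length(dif) - 1L, mean = 0))
    if (stats::sd(dif) == 0)
      stop("zero variance: t statistic undefined")
    ht <- stats::t.test(values, values2, paired = TRUE,
                        alternative = "two.sided")
  } else {
    if (stats::sd(values) == 0)
      stop("zero variance: t statistic undefined")
    ht <- stats::t.test(values, mu = 0, alternative = "greater")
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean = unname(ht$estimate[1]))
}

#' Compare two simulation results
#'
#' Convenience wrapper computing the full metric set between two
#' `ced_result`s at their final snapshot: RMSD, the two principal
#' directions and their angle, penetration lengths, and the overlap
#' fraction.
#'
#' @param resA,resB [run_case()] results on one grid.
#' @return A list of metrics.
#' @export
compare_results <- function(resA, resB) {
  stopifnot(inherits(resA, "ced_result"), inherits(resB, "ced_result"))
  cA <- resA$transport$conc[[length(resA$transport$conc)]]
  cB <- resB$transport$conc[[length(resB$transport$conc)]]
  c0 <- resA$catheter$c0_si
  cmf <- resA$config$c_min_fraction
  regA <- infusion_region(cA, c0, cmf)
  regB <- infusion_region(cB, c0, cmf)
  dA <- if (regA$n >= 2) principal_direction(regA) else rep(NA_real_, 3)
  dB <- if (regB$n >= 2) principal_direction(regB) else rep(NA_real_, 3)
  list(rmsd = rmsd(cA, cB, c0, cmf),
       direction_A = dA, direction_B = dB,
       theta_deg = if (!anyNA(dA) && !anyNA(dB)) angle_between(dA, dB)
       else NA_real_,
       L_max_A = if (regA$n > 0 && !anyNA(dA))
         penetration_length(regA, dA) else 0,
       L_max_B = if (regB$n > 0 && !anyNA(dB))
         penetration_length(regB, dB) else 0,
       overlap_pct = overlap_fraction(regA, regB),
       volume_A = regA$volume, volume_B = regB$volume)
}
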