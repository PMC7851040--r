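#' Segment brain tissue from FA and free-water maps
#'
#' Thresholding rules dividing the model into tissue classes:
#' cerebrospinal fluid where `vf_water > 0.99` (tested first — a
#' flowing-water voxel can also have low FA, and the FA thresholds are
#' meaningful only for parenchyma), else white matter where
#' `0.23 < FA < 1`, else grey matter where `0 <= FA <= 0.23` (the grey
#' matter interval is closed at its top boundary by convention, so FA
#' exactly 0.23 is grey matter).  Voxels outside the mask are background.
#'
#' @param fa [scalar_volume()] of fractional anisotropy in `[0, 1]`.
#' @param vf_water [scalar_volume()] of free-water fractions, same grid.
#' @param constants [tissue_constants()] holding the two thresholds.
#' @return An object of class `tissue_labels`: an integer array with
#'   levels `BACKGROUND` (0), `GM` (1), `WM` (2), `CSF` (3) plus grid
#'   metadata.
#' @export
segment_tissue <- function(fa, vf_water, constants = tissue_constants()) {
  stopifnot(inherits(fa, "scalar_volume"),
            inherits(vf_water, "scalar_volume"))
  stop_if_grid_mismatch(fa, vf_water)
  mask <- fa$mask & vf_water$mask
  lab <- array(0L, dim(fa$data))
  csf <- mask & vf_water$data > constants$vf_water_csf
  wm <- mask & !csf & fa$data > constants$fa_gm_wm & fa$data < 1
  gm <- mask & !csf & !wm
  lab[gm] <- 1L; lab[wm] <- 2L; lab[csf] <- 3L
  structure(list(labels = lab, mask = mask,
                 levels = c(BACKGROUND = 0L, GM = 1L, WM = 2L, CSF = 3L),
                 voxel_size = fa$voxel_size, affine = fa$affine),
            class = "tissue_labels")
}

#' @export
print.tissue_labels <- function(x, ...) {
  counts <- vapply(x$levels, function(l) sum(x$labels == l), integer(1))
  cat("<tissue_labels>", paste(dim(x$labels), collapse = " x "), "grid:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      "\n")
  invisible(x)
}
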