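#' Axis calibration for rasterized HSQC spectra
#'
#' Maps chemical-shift coordinates (1H and 13C, in ppm) onto a fixed pixel
#' raster. The default windows are 1H in \[0, 10\] ppm and 13C in
#' \[0, 182.857\] ppm so that a 512-px raster realizes 51.2 px/ppm in the
#' proton dimension and 2.8 px/ppm in the carbon dimension; smaller rasters
#' keep the same windows at proportionally lower density.
#'
#' Image orientation follows NMR convention: 1H shifts increase from right to
#' left (column index grows as h_ppm decreases) and 13C shifts increase from
#' top to bottom (row index grows as c_ppm increases).
#'
#' @param h_min_ppm,h_max_ppm Proton chemical-shift window (ppm).
#' @param c_min_ppm,c_max_ppm Carbon chemical-shift window (ppm).
#' @param width_px,height_px Raster dimensions in pixels.
#' @return An object of class `axis_calibration`.
#' @examples
#' cal <- axis_calibration(width_px = 512, height_px = 512)
#' cal$width_px / (cal$h_max_ppm - cal$h_min_ppm)  # 51.2 px/ppm
#' @export
axis_calibration <- function(h_min_ppm = 0, h_max_ppm = 10,
                             c_min_ppm = 0, c_max_ppm = 1280 / 7,
                             width_px = 512L, height_px = 512L) {
  if (!(h_max_ppm > h_min_ppm)) stop("h_max_ppm must exceed h_min_ppm")
  if (!(c_max_ppm > c_min_ppm)) stop("c_max_ppm must exceed c_min_ppm")
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 1L || height_px < 1L) stop("raster dimensions must be >= 1 px")
  structure(list(h_min_ppm = h_min_ppm, h_max_ppm = h_max_ppm,
                 c_min_ppm = c_min_ppm, c_max_ppm = c_max_ppm,
                 width_px = width_px, height_px = height_px),
            class = "axis_calibration")
}

#' Default calibration for a square raster
#'
#' Convenience wrapper keeping the standard shift windows (1H 0-10 ppm,
#' 13C 0-182.857 ppm) at an arbitrary square raster size.
#'
#' @param input_side Side length of the square raster in pixels.
#' @return An `axis_calibration`.
#' @export
default_calibration <- function(input_side = 512L) {
  axis_calibration(width_px = input_side, height_px = input_side)
}

#' @export
print.axis_calibration <- function(x, ...) {
  cat(sprintf("HSQC axis calibration: %d x %d px, 1H [%g, %g] ppm (%.2f px/ppm), 13C [%g, %g] ppm (%.2f px/ppm)\n",
              x$width_px, x$height_px,
              x$h_min_ppm, x$h_max_ppm, x$width_px / (x$h_max_ppm - x$h_min_ppm),
              x$c_min_ppm, x$c_max_ppm, x$height_px / (x$c_max_ppm - x$c_min_ppm)))
  invisible(x)
}

## ppm -> pixel index (1-based), floor binning with the exact upper boundary
## clamped into the last bin.
ppm_to_col <- function(h_ppm, cal) {
  px <- floor((cal$h_max_ppm - h_ppm) * cal$width_px / (cal$h_max_ppm - cal$h_min_ppm))
  pmin(pmax(px, 0), cal$width_px - 1L) + 1L
}

ppm_to_row <- function(c_ppm, cal) {
  px <- floor((c_ppm - cal$c_min_ppm) * cal$height_px / (cal$c_max_ppm - cal$c_min_ppm))
  pmin(pmax(px, 0), cal$height_px - 1L) + 1L
}
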