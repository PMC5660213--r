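#' Binary spectrum image
#'
#' A rasterized HSQC spectrum: a `height_px x width_px` matrix with entries in
#' {0, 1}, where 1 marks foreground ("black": signal or noise) and 0 the
#' spectral background, together with its axis calibration.
#'
#' @param pixels Numeric matrix with values in {0, 1}.
#' @param calibration An [axis_calibration()] whose dimensions match `pixels`.
#' @return An object of class `spectrum_image`.
#' @export
spectrum_image <- function(pixels, calibration) {
  stopifnot(inherits(calibration, "axis_calibration"))
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != calibration$height_px || ncol(pixels) != calibration$width_px) {
    stop(sprintf("pixel matrix is %d x %d but calibration expects %d x %d",
                 nrow(pixels), ncol(pixels), calibration$height_px, calibration$width_px))
  }
  if (!all(pixels %in% c(0, 1))) stop("spectrum_image pixels must be binary (0/1)")
  structure(list(pixels = pixels, calibration = calibration),
            class = "spectrum_image")
}

#' @export
print.spectrum_image <- function(x, ...) {
  cat(sprintf("spectrum_image: %d x %d px, %d foreground pixels (%.2f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

is_binary_matrix <- function(m) is.matrix(m) && all(m %in% c(0, 1))
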