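#' Load a grayscale HSQC spectrum image
#'
#' Reads a single-channel PNG and returns normalized *darkness* values in
#' \[0, 1\] (1 = black). PNG stores lightness, so the loader inverts it: the
#' convention throughout the package is that foreground (signal and noise,
#' printed black) carries the value 1. The result is not yet binary; pass it
#' through [binarize()].
#'
#' @param path Path to a PNG file.
#' @param calibration Expected [axis_calibration()]; the image must match its
#'   pixel dimensions exactly.
#' @return A list with `pixels` (darkness matrix in \[0,1\]) and `calibration`.
#' @export
load_spectrum_image <- function(path, calibration) {
  if (!file.exists(path)) stop(sprintf("spectrum image not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    ## flatten RGB(A) to luminance; alpha ignored
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  if (nrow(img) != calibration$height_px || ncol(img) != calibration$width_px) {
    stop(sprintf("calibration error: expected %d x %d px, found %d x %d in %s",
                 calibration$height_px, calibration$width_px,
                 nrow(img), ncol(img), path))
  }
  list(pixels = 1 - img, calibration = calibration)
}

#' Write a binary spectrum image as PNG
#'
#' Inverse of [load_spectrum_image()]: foreground (1) is written black.
#'
#' @param image A [spectrum_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_spectrum_image <- function(image, path) {
  stopifnot(inherits(image, "spectrum_image"))
  png::writePNG(1 - image$pixels, target = path)
  invisible(path)
}

#' Binarize a grayscale raster
#'
#' Converts normalized darkness values into the black/white representation the
#' network consumes: pixel = 1 where darkness >= `threshold`, else 0.
#' Idempotent on already-binary input for any threshold in (0, 1).
#'
#' @param image A list with `pixels` in \[0,1\] and `calibration` (as returned
#'   by [load_spectrum_image()]), or a bare matrix plus `calibration`.
#' @param threshold Scalar in (0, 1). Default 0.5.
#' @param calibration Required when `image` is a bare matrix.
#' @return A [spectrum_image()].
#' @export
binarize <- function(image, threshold = 0.5, calibration = NULL) {
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold < 1)) {
    stop("threshold must be a scalar strictly inside (0, 1)")
  }
  if (is.matrix(image)) {
    pixels <- image
    if (is.null(calibration)) stop("calibration required for a bare matrix")
  } else {
    pixels <- image$pixels
    calibration <- image$calibration
  }
  if (any(pixels < 0 | pixels > 1)) stop("grayscale values must lie in [0, 1]")
  spectrum_image((pixels >= threshold) * 1, calibration)
}

#' Cross-shaped 3x3 median filter
#'
#' Despeckling step applied to every binary spectrum before it reaches the
#' network: each pixel is replaced by the median over the 5-element cross
#' neighbourhood (self, up, down, left, right), which removes isolated
#' salt-and-pepper pixels while preserving contiguous peak footprints.
#' Borders use edge replication.
#'
#' @param image A binary [spectrum_image()].
#' @return The filtered [spectrum_image()].
#' @export
median_filter_cross <- function(image) {
  stopifnot(inherits(image, "spectrum_image"))
  p <- image$pixels
  nr <- nrow(p); nc <- ncol(p)
  up    <- p[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- p[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- p[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- p[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  ## median of 5 binary values = 1 iff at least 3 are 1
  s <- p + up + down + left + right
  spectrum_image((s >= 3) * 1, image$calibration)
}

#' Rasterize an HSQC peak list
#'
#' Places each 1H-13C correlation onto the pixel grid:
#' `column = floor((h_max - h_ppm) * width / (h_max - h_min))`,
#' `row = floor((c_ppm - c_min) * height / (c_max - c_min))` (0-based,
#' clamped into range at the exact upper boundary), then paints a square
#' footprint of side `footprint_px` centred on that pixel (clipped at the
#' image border).
#'
#' @param peaks A `peak_list` (see [peak_list()]) or a data frame with columns
#'   `h_ppm`, `c_ppm` and optionally `intensity`.
#' @param calibration An [axis_calibration()].
#' @param footprint_px Odd positive integer; side of the painted square.
#' @return A binary [spectrum_image()].
#' @export
rasterize_peaklist <- function(peaks, calibration, footprint_px = 3L) {
  df <- as_peak_df(peaks)
  if (nrow(df) == 0L) stop("cannot rasterize an empty peak list")
  footprint_px <- as.integer(footprint_px)
  if (footprint_px < 1L || footprint_px %% 2L == 0L) {
    stop("footprint_px must be a positive odd integer")
  }
  out_h <- df$h_ppm < calibration$h_min_ppm | df$h_ppm > calibration$h_max_ppm
  out_c <- df$c_ppm < calibration$c_min_ppm | df$c_ppm > calibration$c_max_ppm
  if (any(out_h | out_c)) {
    bad <- which(out_h | out_c)[1L]
    stop(sprintf("peak outside calibration window: h=%g ppm, c=%g ppm",
                 df$h_ppm[bad], df$c_ppm[bad]))
  }
  pix <- matrix(0, calibration$height_px, calibration$width_px)
  cols <- ppm_to_col(df$h_ppm, calibration)
  rows <- ppm_to_row(df$c_ppm, calibration)
  half <- (footprint_px - 1L) %/% 2L
  for (i in seq_len(nrow(df))) {
    rr <- max(1L, rows[i] - half):min(calibration$height_px, rows[i] + half)
    cc <- max(1L, cols[i] - half):min(calibration$width_px, cols[i] + half)
    pix[rr, cc] <- 1
  }
  spectrum_image(pix, calibration)
}

#' HSQC peak list
#'
#' One row per 1H-13C correlation signal.
#'
#' @param compound_id Identifier for the compound.
#' @param h_ppm,c_ppm Numeric vectors of proton and carbon shifts (ppm).
#' @param intensity Non-negative relative intensities; default 1.
#' @return A `peak_list`: a data frame with attribute `compound_id`.
#' @export
peak_list <- function(compound_id, h_ppm, c_ppm, intensity = 1) {
  stopifnot(length(h_ppm) == length(c_ppm))
  intensity <- rep_len(intensity, length(h_ppm))
  if (any(intensity < 0)) stop("peak intensities must be non-negative")
  if (anyDuplicated(cbind(h_ppm, c_ppm))) {
    stop("duplicate peak positions in peak list")
  }
  df <- data.frame(h_ppm = h_ppm, c_ppm = c_ppm, intensity = intensity)
  attr(df, "compound_id") <- compound_id
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Read a peak-list CSV (columns h_ppm, c_ppm, optional intensity)
#'
#' @param path CSV path.
#' @param compound_id Identifier; defaults to the file name.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, compound_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("h_ppm", "c_ppm") %in% names(df))) {
    stop("peak-list CSV must have columns h_ppm and c_ppm")
  }
  if (is.null(df$intensity)) df$intensity <- 1
  peak_list(compound_id, df$h_ppm, df$c_ppm, df$intensity)
}

as_peak_df <- function(peaks) {
  if (inherits(peaks, "peak_list") || is.data.frame(peaks)) {
    as.data.frame(peaks)
  } else {
    stop("peaks must be a peak_list or data frame")
  }
}

#' Dataset manifest
#'
#' The labelled index of a spectral corpus: one row per spectrum with its
#' family label (structurally related compounds share a label, mirroring the
#' same-publication-same-class rule used to label real corpora).
#'
#' @param spectrum_id Unique identifiers.
#' @param path Image paths (or `NA` for in-memory datasets).
#' @param family Non-empty family labels.
#' @param compound Compound names (optional, default `""`).
#' @param source Free-text provenance notes (optional, default `""`).
#' @return A `dataset_manifest` data frame.
#' @export
dataset_manifest <- function(spectrum_id, path = NA_character_, family,
                             compound = "", source = "") {
  spectrum_id <- as.character(spectrum_id)
  family <- as.character(family)
  if (anyDuplicated(spectrum_id)) stop("spectrum_ids must be unique")
  if (any(!nzchar(family))) stop("family labels must be non-empty")
  df <- data.frame(spectrum_id = spectrum_id,
                   path = rep_len(as.character(path), length(spectrum_id)),
                   family = family,
                   compound = rep_len(as.character(compound), length(spectrum_id)),
                   source = rep_len(as.character(source), length(spectrum_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Read / write a manifest TSV
#'
#' Columns: spectrum_id, path, family, compound, source.
#'
#' @param path TSV path.
#' @return [read_manifest()] returns a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("spectrum_id", "path", "family", "compound", "source")
  if (!all(need %in% names(df))) {
    stop("manifest TSV must have columns ", paste(need, collapse = ", "))
  }
  dataset_manifest(df$spectrum_id, df$path, df$family, df$compound, df$source)
}

#' @param manifest A `dataset_manifest`.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only compound families with enough spectra
#'
#' Reproduces the corpus-construction rule that defines the
#' minimum-membership datasets (e.g. all families with at least 5, or at
#' least 10, spectra). Record order is preserved.
#'
#' @param manifest A `dataset_manifest`.
#' @param min_members Positive integer; smallest family size retained.
#' @return The filtered `dataset_manifest`.
#' @export
filter_families <- function(manifest, min_members) {
  min_members <- as.integer(min_members)
  if (is.na(min_members) || min_members < 1L) {
    stop("min_members must be a positive integer")
  }
  sizes <- table(manifest$family)
  keep <- manifest$family %in% names(sizes)[sizes >= min_members]
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Family size table of a manifest
#' @param manifest A `dataset_manifest`.
#' @return Named integer vector of member counts, decreasing.
#' @export
family_sizes <- function(manifest) {
  sort(table(manifest$family), decreasing = TRUE)
}

#' Number of distinguishable peak positions on an HSQC grid
#'
#' With shifts resolvable to `h_res` ppm over \[`h_lo`, `h_hi`\] in the proton
#' dimension and `c_res` over \[`c_lo`, `c_hi`\] in the carbon dimension, the
#' spectrum offers `round((h_hi-h_lo)/h_res) * round((c_hi-c_lo)/c_res)`
#' distinguishable cross-peak positions — the combinatorial capacity that
#' makes an HSQC spectrum a discriminating molecular fingerprint.
#'
#' @param h_lo,h_hi,h_res Proton window and resolution (ppm).
#' @param c_lo,c_hi,c_res Carbon window and resolution (ppm).
#' @return Integer-valued count.
#' @examples
#' grid_capacity(0.5, 9.5, 0.02, 10, 215, 0.1)  # 922500
#' @export
grid_capacity <- function(h_lo, h_hi, h_res, c_lo, c_hi, c_res) {
  if (!(h_hi > h_lo) || !(c_hi > c_lo)) stop("window upper bound must exceed lower bound")
  if (h_res <= 0 || c_res <= 0) stop("resolutions must be positive")
  round((h_hi - h_lo) / h_res) * round((c_hi - c_lo) / c_res)
}

#' Non-uniform sampling density
#'
#' Fraction of indirect-dimension increments actually acquired in a
#' non-uniformly sampled 2D experiment.
#'
#' @param sampled_increments,total_increments Counts of acquired and nominal
#'   t1 increments.
#' @return `sampled_increments / total_increments`.
#' @examples
#' nus_density(32, 128)  # 0.25
#' @export
nus_density <- function(sampled_increments, total_increments) {
  if (total_increments < 1) stop("total_increments must be >= 1")
  if (sampled_increments < 0 || sampled_increments > total_increments) {
    stop("sampled_increments must lie in [0, total_increments]")
  }
  sampled_increments / total_increments
}
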