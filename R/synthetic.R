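#' Perturbation model for within-family spectral variability
#'
#' Controls how members of a compound family differ from their shared peak
#' template, emulating what makes real within-family HSQC spectra diverge:
#' small chemical-shift displacements (solvent and matrix effects), peaks
#' appearing or vanishing with single functional-group changes, and
#' salt-and-pepper pixel noise from thresholded plots.
#'
#' Defaults: jitter SDs 0.03 ppm (1H) and 0.3 ppm (13C) — the order of
#' solvent-induced shift changes; each template peak dropped with
#' probability 0.1; on average one spurious peak added; 0.2% of pixels
#' flipped. Chosen to keep families separable yet overlapping.
#'
#' @param h_jitter_sd,c_jitter_sd Gaussian shift jitter SDs (ppm).
#' @param peak_drop_prob Per-peak deletion probability.
#' @param peak_add_rate Poisson mean of spurious added peaks.
#' @param footprint_px Odd integer; painted square side per peak.
#' @param salt_pepper_rate Per-pixel flip probability.
#' @return A `perturbation_model`.
#' @export
perturbation_model <- function(h_jitter_sd = 0.03, c_jitter_sd = 0.3,
                               peak_drop_prob = 0.1, peak_add_rate = 1.0,
                               footprint_px = 3L, salt_pepper_rate = 0.002) {
  stopifnot(h_jitter_sd >= 0, c_jitter_sd >= 0,
            peak_drop_prob >= 0, peak_drop_prob <= 1,
            peak_add_rate >= 0,
            salt_pepper_rate >= 0, salt_pepper_rate <= 1)
  footprint_px <- as.integer(footprint_px)
  if (footprint_px < 1L || footprint_px %% 2L == 0L) {
    stop("footprint_px must be a positive odd integer")
  }
  structure(list(h_jitter_sd = h_jitter_sd, c_jitter_sd = c_jitter_sd,
                 peak_drop_prob = peak_drop_prob, peak_add_rate = peak_add_rate,
                 footprint_px = footprint_px, salt_pepper_rate = salt_pepper_rate),
            class = "perturbation_model")
}

#' Generate compound-family peak templates
#'
#' Each family is defined by a template peak list drawn uniformly inside the
#' calibration windows, with a minimum inter-peak separation of two peak
#' footprints (Chebyshev distance in pixel space) so that cross-peaks do not
#' merge. Family sizes are drawn from a truncated geometric distribution over
#' `size_range`: most families sit near the minimum membership and few near
#' the maximum, matching the right-skewed family-size distribution of real
#' natural-product corpora.
#'
#' @param n_families Number of families.
#' @param peaks_range Length-2 integer range of template peak counts
#'   (minimum 3 peaks).
#' @param size_range Length-2 integer range of family sizes (default 5-25).
#' @param calibration An [axis_calibration()].
#' @param seed Integer seed; output is deterministic given it.
#' @param footprint_px Footprint used for the separation rule.
#' @param size_skew Geometric decay parameter in (0, 1); larger = more skew.
#' @return A list of `family_template` objects (fields `family_id`,
#'   `template_peaks`, `n_members`).
#' @export
generate_templates <- function(n_families, peaks_range = c(8L, 30L),
                               size_range = c(5L, 25L),
                               calibration = default_calibration(),
                               seed = 1L, footprint_px = 3L,
                               size_skew = 0.25) {
  stopifnot(n_families >= 1, peaks_range[1] >= 3, peaks_range[2] >= peaks_range[1],
            size_range[1] >= 1, size_range[2] >= size_range[1])
  with_seed(seed, {
    sizes <- sample_family_sizes(n_families, size_range, size_skew)
    lapply(seq_len(n_families), function(f) {
      n_peaks <- if (peaks_range[1] == peaks_range[2]) peaks_range[1] else
        sample(peaks_range[1]:peaks_range[2], 1L)
      pk <- place_separated_peaks(n_peaks, calibration, 2L * footprint_px)
      structure(list(family_id = sprintf("fam%03d", f),
                     template_peaks = peak_list(sprintf("fam%03d_template", f),
                                                pk$h_ppm, pk$c_ppm),
                     n_members = sizes[f]),
                class = "family_template")
    })
  })
}

sample_family_sizes <- function(n, size_range, skew) {
  sizes <- size_range[1]:size_range[2]
  if (length(sizes) == 1L) return(rep(sizes, n))
  prob <- (1 - skew)^(sizes - size_range[1])
  sizes[sample.int(length(sizes), n, replace = TRUE, prob = prob / sum(prob))]
}

place_separated_peaks <- function(n_peaks, cal, min_sep_px, max_tries = 2000L) {
  h <- numeric(0); c_ <- numeric(0)
  px_per_h <- cal$width_px / (cal$h_max_ppm - cal$h_min_ppm)
  px_per_c <- cal$height_px / (cal$c_max_ppm - cal$c_min_ppm)
  tries <- 0L
  while (length(h) < n_peaks) {
    if (tries >= max_tries) {
      stop(sprintf("calibration window too small to place %d peaks at %d px separation",
                   n_peaks, min_sep_px))
    }
    tries <- tries + 1L
    hh <- stats::runif(1, cal$h_min_ppm, cal$h_max_ppm)
    cc <- stats::runif(1, cal$c_min_ppm, cal$c_max_ppm)
    if (length(h) == 0L ||
        all(pmax(abs(hh - h) * px_per_h, abs(cc - c_) * px_per_c) >= min_sep_px)) {
      h <- c(h, hh); c_ <- c(c_, cc)
    }
  }
  list(h_ppm = h, c_ppm = c_)
}

#' Render one family member from its template
#'
#' Applies the perturbation model to a template: each peak is independently
#' dropped with `peak_drop_prob` (the drop mask is redrawn until at least one
#' peak survives — a spectrum with no peaks would have been discarded from
#' any real corpus), surviving peaks are jittered by Gaussian ppm offsets
#' clamped into the calibration window, Poisson-many spurious peaks are added
#' uniformly in-window, the peak list is rasterized, and finally pixels are
#' flipped independently at `salt_pepper_rate`.
#'
#' @param template A `family_template`.
#' @param model A [perturbation_model()].
#' @param calibration An [axis_calibration()].
#' @param seed Integer seed; deterministic given it.
#' @return A binary [spectrum_image()].
#' @export
render_member <- function(template, model, calibration, seed) {
  tp <- as.data.frame(template$template_peaks)
  with_seed(seed, {
    repeat {
      keep <- stats::runif(nrow(tp)) >= model$peak_drop_prob
      if (any(keep)) break
    }
    h <- tp$h_ppm[keep] + stats::rnorm(sum(keep), 0, model$h_jitter_sd)
    c_ <- tp$c_ppm[keep] + stats::rnorm(sum(keep), 0, model$c_jitter_sd)
    h <- pmin(pmax(h, calibration$h_min_ppm), calibration$h_max_ppm)
    c_ <- pmin(pmax(c_, calibration$c_min_ppm), calibration$c_max_ppm)
    n_add <- stats::rpois(1L, model$peak_add_rate)
    if (n_add > 0L) {
      h <- c(h, stats::runif(n_add, calibration$h_min_ppm, calibration$h_max_ppm))
      c_ <- c(c_, stats::runif(n_add, calibration$c_min_ppm, calibration$c_max_ppm))
    }
    img <- rasterize_peaklist(data.frame(h_ppm = h, c_ppm = c_, intensity = 1),
                              calibration, model$footprint_px)
    if (model$salt_pepper_rate > 0) {
      flip <- stats::runif(length(img$pixels)) < model$salt_pepper_rate
      img$pixels[flip] <- 1 - img$pixels[flip]
    }
    img
  })
}

#' Build a labelled synthetic HSQC dataset
#'
#' Renders every member of every family and applies the same preprocessing
#' real inputs receive (the cross-shaped median filter), so synthetic and
#' real spectra flow through identical downstream code.
#'
#' @param templates Output of [generate_templates()].
#' @param model A [perturbation_model()].
#' @param calibration An [axis_calibration()].
#' @param seed Integer master seed; each member's render seed derives from
#'   (seed, family index, member index).
#' @return A list with `manifest` (a `dataset_manifest`) and `images` (a
#'   named list of [spectrum_image()] keyed by spectrum_id, in manifest order).
#' @export
build_dataset <- function(templates, model = perturbation_model(),
                          calibration = default_calibration(), seed = 1L) {
  if (length(templates) == 0L) stop("templates must be non-empty")
  ids <- character(0); fam <- character(0)
  images <- list()
  for (f in seq_along(templates)) {
    tpl <- templates[[f]]
    for (j in seq_len(tpl$n_members)) {
      img <- render_member(tpl, model, calibration, derive_seed(seed, f, j))
      img <- median_filter_cross(img)
      id <- sprintf("%s_m%02d", tpl$family_id, j)
      ids <- c(ids, id); fam <- c(fam, tpl$family_id)
      images[[id]] <- img
    }
  }
  manifest <- dataset_manifest(ids, NA_character_, fam,
                               compound = ids, source = "synthetic")
  list(manifest = manifest, images = images)
}

#' White Gaussian noise field via 2D FFT
#'
#' Simulates spectral noise: an i.i.d. standard-Gaussian matrix is
#' transformed by a 2D fast Fourier transform and its magnitude normalized to
#' \[0, 1\]. The FFT introduces the long-range correlation structure typical
#' of transformed instrument noise, as opposed to independent pixel noise.
#'
#' @param height,width Field dimensions (pixels).
#' @param seed Integer seed.
#' @return A `height x width` matrix with values in \[0, 1\].
#' @export
white_noise_field <- function(height, width, seed) {
  stopifnot(height >= 1, width >= 1)
  m <- with_seed(seed, matrix(stats::rnorm(height * width), height, width))
  mag <- Mod(stats::fft(m))
  rng <- range(mag)
  if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else mag * 0
}

#' Inject FFT-structured noise into a binary spectrum
#'
#' Flips the pixels where a [white_noise_field()] exceeds its
#' `(1 - fraction)` quantile, i.e. the `round(fraction * n_pixels)` largest
#' field values (ties resolved deterministically by pixel index). The noise
#' intensity is measured exactly as altered pixels over total pixels.
#'
#' @param image A binary [spectrum_image()].
#' @param fraction Target fraction of altered pixels in \[0, 1\].
#' @param seed Integer seed for the noise field.
#' @return A list with `image` (noisy [spectrum_image()]) and
#'   `realized_fraction`.
#' @export
inject_noise <- function(image, fraction, seed) {
  stopifnot(inherits(image, "spectrum_image"), fraction >= 0, fraction <= 1)
  n <- length(image$pixels)
  n_flip <- round(fraction * n)
  if (n_flip == 0L) {
    return(list(image = image, realized_fraction = 0))
  }
  field <- white_noise_field(nrow(image$pixels), ncol(image$pixels), seed)
  idx <- order(field, decreasing = TRUE)[seq_len(n_flip)]
  out <- image
  out$pixels[idx] <- 1 - out$pixels[idx]
  list(image = out, realized_fraction = n_flip / n)
}

#' Noise-robustness protocol
#'
#' The noise intensity is increased along a finite arithmetic progression of
#' `n_levels` steps up to `max_fraction`, and at each level the noise field
#' is re-randomized `n_reps` times. The default 140 levels x 100 replicates
#' yield 14,000 noisy spectra per compound.
#'
#' @param n_levels Number of intensity steps (default 140).
#' @param max_fraction Fraction of pixels altered at the top level
#'   (default 0.5: half the raster is noise).
#' @param n_reps Replicates per level (default 100).
#' @param seed Integer master seed.
#' @return A `noise_protocol`.
#' @export
noise_protocol <- function(n_levels = 140L, max_fraction = 0.5,
                           n_reps = 100L, seed = 1L) {
  stopifnot(n_levels >= 1, n_reps >= 1, max_fraction > 0, max_fraction <= 1)
  structure(list(n_levels = as.integer(n_levels), max_fraction = max_fraction,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "noise_protocol")
}

#' Expand a noise protocol into its schedule
#'
#' @param protocol A [noise_protocol()].
#' @return A data frame with one row per (level, replicate): `level_index`,
#'   `fraction` (arithmetic progression from `max_fraction / n_levels` to
#'   `max_fraction`), `rep_index`, and a distinct derived `seed`.
#' @export
noise_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "noise_protocol"))
  fractions <- protocol$max_fraction * seq_len(protocol$n_levels) / protocol$n_levels
  grid <- expand.grid(rep_index = seq_len(protocol$n_reps),
                      level_index = seq_len(protocol$n_levels))
  data.frame(level_index = grid$level_index,
             fraction = fractions[grid$level_index],
             rep_index = grid$rep_index,
             seed = mapply(function(l, r) derive_seed(protocol$seed, l, r),
                           grid$level_index, grid$rep_index))
}
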