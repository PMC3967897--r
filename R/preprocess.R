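#' Integrating-sphere measurement of one leaf
#'
#' Bundles the raw per-band radiances needed to reduce one leaf measurement:
#' the sample radiance, the radiance reflected by the white reference panel,
#' the stray-light radiance recorded with a light trap behind the input port,
#' and the panel's absolute reflectance supplied by its manufacturer.
#'
#' @param sample_radiance,white_radiance,stray_radiance numeric vectors of
#'   per-band radiance (arbitrary counts), all on `wavelength`.
#' @param panel_reflectance per-band absolute reflectance of the white
#'   reference panel, fractions in `[0, 1]`. A scalar is recycled.
#' @param wavelength wavelength axis in nm.
#' @return An object of class `sphere_measurement`.
#' @export
sphere_measurement <- function(sample_radiance, white_radiance, stray_radiance,
                               panel_reflectance, wavelength) {
  check_wavelength_axis(wavelength)
  n <- length(wavelength)
  if (length(panel_reflectance) == 1L)
    panel_reflectance <- rep(panel_reflectance, n)
  vecs <- list(sample_radiance = sample_radiance,
               white_radiance = white_radiance,
               stray_radiance = stray_radiance,
               panel_reflectance = panel_reflectance)
  for (nm in names(vecs))
    if (length(vecs[[nm]]) != n)
      stop(nm, " must have one value per band (", n, ")")
  if (any(panel_reflectance < 0 | panel_reflectance > 1))
    stop("panel_reflectance must lie in [0, 1]")
  structure(c(vecs, list(wavelength = as.numeric(wavelength))),
            class = "sphere_measurement")
}

#' Reduce raw sphere radiance to absolute reflectance
#'
#' Stray light is subtracted from the sample and the white-panel radiance;
#' the ratio is the reflectance relative to the panel, which the panel's
#' known absolute reflectance converts to absolute units:
#' `((sample - stray) / (white - stray)) * panel_reflectance`.
#' The identical formula applies to transmittance measurements.
#'
#' @param m a [sphere_measurement()].
#' @return Numeric vector of per-band absolute reflectance.
#' @export
normalize_reflectance <- function(m) {
  stopifnot(inherits(m, "sphere_measurement"))
  denom <- m$white_radiance - m$stray_radiance
  bad <- which(denom == 0)
  if (length(bad) > 0L)
    stop("degenerate reference: white minus stray radiance is zero at band(s) ",
         paste(m$wavelength[utils::head(bad, 5L)], collapse = ", "), " nm")
  (m$sample_radiance - m$stray_radiance) / denom * m$panel_reflectance
}

#' Savitzky-Golay smoothing with split filter windows
#'
#' Each spectrum is smoothed twice with a local least-squares polynomial
#' filter of the given order: once with window `window_a_nm` and once with
#' `window_b_nm`. The output is stitched from the two runs at `boundary_nm`:
#' bands at or below the boundary take the narrow-window result, bands above
#' it the wide-window result. Running both filters over the full spectrum
#' before stitching avoids edge artifacts at the seam. Spectrum ends are
#' fitted by a least-squares polynomial over the leading/trailing window
#' (no mirror padding), so polynomials up to the filter order pass through
#' unchanged everywhere, edges included.
#'
#' Window widths are quoted in nm and converted to sample counts on the
#' axis's uniform step; non-uniform axes are rejected.
#'
#' @param x a [spectral_matrix()] on a uniform wavelength grid.
#' @param order polynomial order of the filter (default 2).
#' @param window_a_nm window width in nm used up to `boundary_nm`
#'   (default 31).
#' @param window_b_nm window width in nm used above `boundary_nm`
#'   (default 51).
#' @param boundary_nm wavelength of the stitch point (default 800).
#' @return The smoothed `spectral_matrix`.
#' @export
savgol_smooth <- function(x, order = 2, window_a_nm = 31, window_b_nm = 51,
                          boundary_nm = 800) {
  stopifnot(inherits(x, "spectral_matrix"))
  steps <- diff(x$wavelength)
  step <- steps[1]
  if (length(steps) > 0 && any(abs(steps - step) > 1e-9))
    stop("smoothing requires a uniform wavelength grid")
  w_a <- window_nm_to_samples(window_a_nm, step, ncol(x$values))
  w_b <- window_nm_to_samples(window_b_nm, step, ncol(x$values))
  if (order >= min(w_a, w_b))
    stop("filter order must be smaller than the window length in samples")
  smooth_two <- function(row) {
    a <- signal::sgolayfilt(row, p = order, n = w_a)
    b <- signal::sgolayfilt(row, p = order, n = w_b)
    ifelse(x$wavelength <= boundary_nm, a, b)
  }
  out <- t(apply(x$values, 1L, smooth_two))
  spectral_matrix(out, x$wavelength, x$kind, plant_ids = plant_ids(x))
}

window_nm_to_samples <- function(window_nm, step, n_bands) {
  w <- window_nm / step
  if (abs(w - round(w)) > 1e-9)
    stop("window of ", window_nm, " nm is not a whole number of samples on a ",
         step, " nm grid")
  w <- as.integer(round(w))
  if (w %% 2L == 0L)
    stop("window of ", window_nm, " nm is an even number of samples; ",
         "Savitzky-Golay windows must be odd")
  if (w > n_bands)
    stop("window of ", w, " samples exceeds the spectrum length (", n_bands, ")")
  w
}

#' Flag spectra with jumps at spectrometer seams
#'
#' Field spectrometers covering a wide range with several detectors can show
#' abrupt level changes exactly at the transitions between detectors when
#' sample and reference were measured under drifting calibration. A spectrum
#' is flagged when the absolute first difference at any configured seam
#' wavelength exceeds the threshold; flagged spectra are conventionally
#' excluded from analysis.
#'
#' @param x a [spectral_matrix()].
#' @param seam_nm wavelengths (nm) of the detector transitions
#'   (default `c(1000, 1800)`).
#' @param threshold jump size, in reflectance units, above which a spectrum
#'   is flagged (default 0.05).
#' @return Named logical vector, `TRUE` for flagged plants.
#' @export
detect_seam_jumps <- function(x, seam_nm = c(1000, 1800), threshold = 0.05) {
  stopifnot(inherits(x, "spectral_matrix"))
  flagged <- rep(FALSE, nrow(x$values))
  for (s in seam_nm) {
    i <- which(x$wavelength == s)
    if (length(i) == 0L || i == 1L) next
    jump <- abs(x$values[, i] - x$values[, i - 1L])
    flagged <- flagged | jump > threshold
  }
  names(flagged) <- plant_ids(x)
  flagged
}
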