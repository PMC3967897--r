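#' Fit a per-band mask calibration from two reference materials
#'
#' Leaves narrower than the sphere input port are measured behind an
#' aperture-reducing mask, which adds its own spectral contribution to the
#' signal. Measuring a white and a black (light-trap) reference both masked
#' and unmasked determines, per band, the affine map from masked signal to
#' true spectrum:
#' `gain = (true_white - true_black) / (masked_white - masked_black)` and
#' `offset = true_white - gain * masked_white`, so both references map
#' exactly onto their true spectra.
#'
#' This two-point affine inversion is the minimal model consistent with a
#' correction "based on the masked and unmasked spectra of two reference
#' materials"; it is exactly testable by round-tripping any affine
#' contamination.
#'
#' @param masked_white,masked_black per-band normalized signal of the white
#'   and black reference measured under the mask.
#' @param true_white,true_black per-band absolute reflectance of the same
#'   references measured unmasked.
#' @param wavelength wavelength axis in nm.
#' @return An object of class `mask_calibration` with per-band `gain` and
#'   `offset`.
#' @export
fit_mask_calibration <- function(masked_white, masked_black,
                                 true_white, true_black, wavelength) {
  check_wavelength_axis(wavelength)
  n <- length(wavelength)
  vecs <- list(masked_white = masked_white, masked_black = masked_black,
               true_white = true_white, true_black = true_black)
  for (nm in names(vecs))
    if (length(vecs[[nm]]) != n)
      stop(nm, " must have one value per band (", n, ")")
  denom <- masked_white - masked_black
  bad <- which(denom == 0)
  if (length(bad) > 0L)
    stop("degenerate references: masked white equals masked black at band(s) ",
         paste(wavelength[utils::head(bad, 5L)], collapse = ", "), " nm")
  gain <- (true_white - true_black) / denom
  offset <- true_white - gain * masked_white
  structure(list(gain = gain, offset = offset,
                 wavelength = as.numeric(wavelength)),
            class = "mask_calibration")
}

#' Apply a mask calibration to a masked leaf measurement
#'
#' The fitted per-band affine map removes the mask's spectral contribution:
#' `corrected = gain * masked + offset`. Corrected values outside `[0, 1]`
#' are kept and flagged via the `out_of_range` attribute.
#'
#' @param leaf_masked per-band normalized signal of the leaf measured under
#'   the mask, on the calibration's axis.
#' @param calibration a [fit_mask_calibration()] result.
#' @return Numeric vector of corrected per-band spectrum with attribute
#'   `out_of_range` (logical).
#' @export
correct_masked_spectrum <- function(leaf_masked, calibration) {
  stopifnot(inherits(calibration, "mask_calibration"))
  if (length(leaf_masked) != length(calibration$wavelength))
    stop("leaf spectrum and calibration are on different axes (",
         length(leaf_masked), " vs ", length(calibration$wavelength), " bands)")
  corrected <- calibration$gain * leaf_masked + calibration$offset
  attr(corrected, "out_of_range") <- corrected < 0 | corrected > 1
  corrected
}
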