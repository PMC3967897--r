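#' Configuration of the synthetic leaf dataset generator
#'
#' The generator emulates the statistical structure the spectra-trait
#' analysis assumes: leaf spectra on a 1-nm grid over 400--1800 nm (1401
#' bands) with Gaussian absorption features whose depths are linear in
#' latent leaf constituents, and measured traits that are imperfectly
#' coupled to the spectrally active constituents.
#'
#' Default features (centre nm / Gaussian width nm / maximum depth):
#' pigment 680/40/0.06, water 1200/50/0.06 and 1450/60/0.12, dry matter
#' 1700/80/0.08 -- a chlorophyll absorption trough in the visible plus the
#' canonical leaf-water and dry-matter bands, on a red-edge-shaped baseline
#' (low visible reflectance rising steeply near 715 nm).
#'
#' `coupling_rho` is the correlation between a measured trait and its
#' spectrally active constituent. With `rho = 1` the trait is exactly the
#' constituent the spectra encode (theoretical validation r-squared 1);
#' smaller values emulate a trait whose spectrally relevant fraction varies
#' across plants, capping the attainable r-squared at `rho^2`. It applies to
#' the coupled traits (N content via the pigment constituent, dry matter
#' content via the dry-matter constituent); P and C content are generated
#' uncoupled.
#'
#' @param n_plants number of plants (default 60).
#' @param wavelength axis in nm (default `400:1800`).
#' @param features data frame with columns `center`, `width`, `max_depth`,
#'   `constituent`; see above for the default.
#' @param coupling_rho trait-constituent coupling in `[0, 1]` (default 0.9).
#' @param noise_sd additive spectral noise standard deviation, reflectance
#'   units (default 0.005).
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_plants = 60,
                             wavelength = 400:1800,
                             features = default_features(),
                             coupling_rho = 0.9,
                             noise_sd = 0.005,
                             seed = 1L) {
  check_wavelength_axis(wavelength)
  stopifnot(is.data.frame(features),
            all(c("center", "width", "max_depth", "constituent") %in%
                  names(features)))
  if (n_plants < 1L) stop("n_plants must be at least 1")
  if (coupling_rho < 0 || coupling_rho > 1)
    stop("coupling_rho must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_plants = as.integer(n_plants),
                 wavelength = as.numeric(wavelength),
                 features = features,
                 coupling_rho = coupling_rho,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_features <- function() {
  data.frame(center = c(680, 1200, 1450, 1700),
             width = c(40, 50, 60, 80),
             max_depth = c(0.06, 0.06, 0.12, 0.08),
             constituent = c("pigment", "water", "water", "dry_matter"),
             stringsAsFactors = FALSE)
}

gaussian_feature <- function(wavelength, center, width) {
  exp(-(wavelength - center)^2 / (2 * width^2))
}

# red-edge shaped baselines: low in the visible, high in the near infrared
baseline_reflectance <- function(wavelength)
  0.15 + 0.35 * stats::plogis((wavelength - 715) / 30)
baseline_transmittance <- function(wavelength)
  0.10 + 0.30 * stats::plogis((wavelength - 715) / 30)

couple_trait <- function(constituent_z, rho, eps, mean, sd)
  mean + sd * (rho * constituent_z + sqrt(1 - rho^2) * eps)

#' Generate a synthetic leaf spectroscopy dataset
#'
#' Per plant, standard-normal latent constituent levels are drawn for every
#' constituent named in the feature table. Reflectance is the baseline minus
#' each feature's Gaussian absorption scaled by `max_depth * (1 + 0.3 z)`
#' (so the mean leaf absorbs the nominal depth and leaves vary around it),
#' plus additive Gaussian noise; transmittance is generated analogously with
#' 0.8 times the reflectance depths and independent noise, then rescaled per
#' plant if needed so that `R + T <= 1`. Absorbance is `1 - R - T` exactly.
#'
#' Traits are affine rescalings of
#' `rho * constituent + sqrt(1 - rho^2) * noise` into plausible positive
#' ranges (N content: mean 20, sd 2 mg/g, coupled to the pigment
#' constituent; dry matter content: mean 250, sd 40 mg/g, coupled to the
#' dry-matter constituent and realized through the fresh/dry mass columns).
#' P content (mean 1.5, sd 0.3 mg/g), C content (mean 450, sd 25 mg/g) and
#' the specific leaf area driver (mean 20, sd 4 mm^2/mg) are uncoupled.
#' The small coefficient of variation keeps the downstream log transform
#' close to linear, so the attainable validation r-squared stays at
#' `coupling_rho^2`.
#'
#' The generator errors if the configuration produces noiseless spectra
#' outside `[0, 1]`.
#'
#' @param config a [generator_config()].
#' @return A list of class `synthetic_dataset`: `reflectance`,
#'   `transmittance`, `absorbance` ([spectral_matrix()] objects), `traits`
#'   (data frame in the trait-table layout), and `truth` with the latent
#'   `constituents` matrix, the `informative_bands` mask (within 2 widths of
#'   any feature), `theoretical_r2 = coupling_rho^2` and the
#'   `trait_constituent` map.
#' @export
simulate_leaf_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_plants
  wl <- config$wavelength
  feats <- config$features
  cons_names <- unique(feats$constituent)
  Z <- matrix(stats::rnorm(n * length(cons_names)), n,
              dimnames = list(NULL, cons_names))

  absorption <- function(depth_scale) {
    A <- matrix(0, n, length(wl))
    for (j in seq_len(nrow(feats))) {
      g <- gaussian_feature(wl, feats$center[j], feats$width[j])
      level <- 1 + 0.3 * Z[, feats$constituent[j]]
      A <- A + outer(level, depth_scale * feats$max_depth[j] * g)
    }
    A
  }
  R0 <- matrix(rep(baseline_reflectance(wl), each = n), n) - absorption(1)
  T0 <- matrix(rep(baseline_transmittance(wl), each = n), n) - absorption(0.8)
  if (any(R0 < 0 | R0 > 1) || any(T0 < 0 | T0 > 1))
    stop("feature depths drive noiseless spectra outside [0, 1]; ",
         "reduce max_depth or raise the baseline")
  R <- R0 + matrix(stats::rnorm(n * length(wl), 0, config$noise_sd), n)
  Tt <- T0 + matrix(stats::rnorm(n * length(wl), 0, config$noise_sd), n)
  # rescale T per plant so that R + T <= 1 at every band
  for (i in seq_len(n)) {
    if (max(R[i, ] + Tt[i, ]) > 1) {
      pos <- Tt[i, ] > 0
      Tt[i, ] <- Tt[i, ] * min(1, min((1 - R[i, pos]) / Tt[i, pos]))
    }
  }
  A <- 1 - R - Tt

  ids <- sprintf("P%03d", seq_len(n))
  rho <- config$coupling_rho
  zcol <- function(nm) if (nm %in% colnames(Z)) Z[, nm] else stats::rnorm(n)
  lnc <- couple_trait(zcol("pigment"), rho, stats::rnorm(n), 20, 2)
  ldmc <- couple_trait(zcol("dry_matter"), rho, stats::rnorm(n), 250, 40)
  ldmc <- pmin(pmax(ldmc, 30), 970)  # keep dry mass within fresh mass
  sla <- pmax(20 + 4 * stats::rnorm(n), 2)
  lpc <- pmax(1.5 + 0.3 * stats::rnorm(n), 0.1)
  lcc <- pmax(450 + 25 * stats::rnorm(n), 50)
  fresh <- stats::rlnorm(n, log(150), 0.3)
  dry <- ldmc / 1000 * fresh
  area <- sla * dry
  traits <- data.frame(plant_id = ids, fresh_mass_mg = fresh,
                       dry_mass_mg = dry, leaf_area_mm2 = area,
                       lnc_mg_g = lnc, lpc_mg_g = lpc, lcc_mg_g = lcc,
                       stringsAsFactors = FALSE)

  informative <- rep(FALSE, length(wl))
  for (j in seq_len(nrow(feats)))
    informative <- informative |
      abs(wl - feats$center[j]) <= 2 * feats$width[j]

  structure(list(
    reflectance = spectral_matrix(R, wl, "reflectance", plant_ids = ids),
    transmittance = spectral_matrix(Tt, wl, "transmittance", plant_ids = ids),
    absorbance = spectral_matrix(A, wl, "absorbance", plant_ids = ids),
    traits = traits,
    truth = list(constituents = Z,
                 informative_bands = informative,
                 theoretical_r2 = rho^2,
                 trait_constituent = c(lnc_mg_g = "pigment",
                                       ldmc = "dry_matter"),
                 config = config)),
    class = "synthetic_dataset")
}

#' Forward-simulate a masked measurement scenario
#'
#' Draws a smooth per-band affine contamination (gain and offset) emulating
#' the spectral contribution of an aperture mask, applies its inverse to
#' known true spectra to produce the masked signals, and emits the masked
#' and unmasked reference spectra needed by [fit_mask_calibration()]. The
#' round trip fit + [correct_masked_spectrum()] recovers the truth to
#' machine precision.
#'
#' @param true_spectra a [spectral_matrix()] of true leaf spectra; default a
#'   small simulated set.
#' @param seed integer seed for the contamination field.
#' @return List with `calibration_inputs` (masked/true white and black
#'   reference vectors), `masked_leaves` (matrix of contaminated signals),
#'   `truth` (the true spectra matrix), `gain`, `offset`, `wavelength`.
#' @export
simulate_mask_scenario <- function(true_spectra = NULL, seed = 1L) {
  if (is.null(true_spectra)) {
    cfg <- generator_config(n_plants = 5, noise_sd = 0, seed = seed)
    true_spectra <- simulate_leaf_dataset(cfg)$reflectance
  }
  stopifnot(inherits(true_spectra, "spectral_matrix"))
  set.seed(seed + 1L)
  wl <- true_spectra$wavelength
  u <- (wl - min(wl)) / max(1, diff(range(wl)))
  # smooth, strictly positive gain and a small offset
  gain <- 0.55 + 0.1 * sin(2 * pi * (u + stats::runif(1))) +
    0.05 * stats::runif(1)
  offset <- 0.05 + 0.03 * cos(2 * pi * (u + stats::runif(1)))
  true_white <- rep(0.99, length(wl))
  true_black <- rep(0.02, length(wl))
  to_masked <- function(r) (r - offset) / gain
  masked_leaves <- t(apply(true_spectra$values, 1L, to_masked))
  list(calibration_inputs = list(masked_white = to_masked(true_white),
                                 masked_black = to_masked(true_black),
                                 true_white = true_white,
                                 true_black = true_black),
       masked_leaves = masked_leaves,
       truth = true_spectra$values,
       gain = gain, offset = offset, wavelength = wl)
}
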