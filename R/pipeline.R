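#' Analysis configuration
#'
#' All reduction and modelling parameters in one validated list. Defaults
#' are the values of the published protocol: crop to 400--1800 nm,
#' second-order Savitzky-Golay smoothing with a 31-nm window up to 800 nm
#' and a 51-nm window above it, band-significance threshold 0.1, at most 15
#' latent variables, seam check at the spectrometer transitions with a 0.05
#' jump threshold.
#'
#' @param ... overrides of the default entries (see `default_run_config()`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$crop_lo_nm < cfg$crop_hi_nm,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$nlv_max >= 1, cfg$sg_order >= 0,
            cfg$max_iterations >= 1)
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(crop_lo_nm = 400, crop_hi_nm = 1800,
       sg_order = 2, window_a_nm = 31, window_b_nm = 51, boundary_nm = 800,
       seam_nm = c(1000, 1800), seam_threshold = 0.05,
       alpha = 0.1, nlv_max = 15, max_iterations = 20,
       scale_bands = FALSE, log_traits = TRUE,
       seed = 1L)
}

#' @rdname run_config
#' @param path a YAML file whose keys override the defaults.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Reduce per-leaf spectra to an analysis-ready per-plant matrix
#'
#' Applies, in order: seam-jump screening (flagged leaves are excluded),
#' cropping to the configured range, split-window Savitzky-Golay smoothing,
#' and per-plant leaf averaging. Input rows are individual leaves already
#' normalized to absolute reflectance or transmittance (see
#' [normalize_reflectance()] for the radiance reduction and
#' [correct_masked_spectrum()] for masked leaves).
#'
#' @param leaves a [spectral_matrix()] whose rows are leaves.
#' @param leaf_plant_ids plant id of each leaf row; defaults to the
#'   `leaf_plant_ids` attribute set by [read_spectra()] on per-leaf tables,
#'   else each row is its own plant.
#' @param config a [run_config()].
#' @return A per-plant `spectral_matrix` with attribute `excluded` naming
#'   the seam-flagged leaves.
#' @export
preprocess_spectra <- function(leaves, leaf_plant_ids = NULL,
                               config = run_config()) {
  stopifnot(inherits(leaves, "spectral_matrix"))
  if (is.null(leaf_plant_ids))
    leaf_plant_ids <- attr(leaves, "leaf_plant_ids") %||% plant_ids(leaves)
  flagged <- detect_seam_jumps(leaves, config$seam_nm, config$seam_threshold)
  excluded <- plant_ids(leaves)[flagged]
  if (any(flagged)) {
    warning("excluding ", sum(flagged), " leaf spectrum/spectra with seam ",
            "jumps: ", paste(excluded, collapse = ", "))
    leaves <- spectral_matrix(leaves$values[!flagged, , drop = FALSE],
                              leaves$wavelength, leaves$kind,
                              plant_ids = plant_ids(leaves)[!flagged])
    leaf_plant_ids <- leaf_plant_ids[!flagged]
  }
  out <- crop_spectra(leaves, config$crop_lo_nm, config$crop_hi_nm)
  out <- savgol_smooth(out, config$sg_order, config$window_a_nm,
                       config$window_b_nm, config$boundary_nm)
  out <- average_leaves(out, leaf_plant_ids)
  attr(out, "excluded") <- excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit trait-prediction models for every trait and spectrum kind
#'
#' For each requested trait column and each spectrum kind: aligns plants,
#' log-transforms the trait (when configured), screens per-band Pearson
#' correlations, and runs [iterative_band_selection()] (leave-one-out
#' validated PLSR with latent-variable selection and significance-driven
#' band cropping). The result is a machine-readable run report.
#'
#' @param spectra named list of per-plant [spectral_matrix()] objects
#'   (e.g. `list(reflectance = ..., transmittance = ..., absorbance = ...)`).
#' @param traits trait data frame with a `plant_id` column; derived traits
#'   are computed via [derive_traits()] when the laboratory columns are
#'   present.
#' @param trait_names trait columns to model; default the seven standard
#'   traits present in the table.
#' @param config a [run_config()].
#' @return A list of class `run_report`; one entry per trait x kind with
#'   elements `trait`, `kind`, `n`, `nlv`, `r2_cal`, `r2_val`, `rmse_cal`,
#'   `rmse_val`, `full_spectrum` (first-iteration metrics), `iterations`,
#'   `stop_reason`, `retained_wavelengths`, `p_values`, `correlations`,
#'   `predictions` (held-out, with observed values), `residuals`.
#' @export
fit_trait_models <- function(spectra, traits,
                             trait_names = NULL, config = run_config()) {
  stopifnot(is.list(spectra), length(spectra) > 0L,
            all(vapply(spectra, inherits, logical(1), "spectral_matrix")))
  if (!"plant_id" %in% names(traits)) stop("traits need a plant_id column")
  lab_cols <- c("fresh_mass_mg", "dry_mass_mg", "leaf_area_mm2",
                "lnc_mg_g", "lpc_mg_g")
  if (all(lab_cols %in% names(traits)) && !"sla" %in% names(traits))
    traits <- derive_traits(traits)
  if (is.null(trait_names)) {
    std <- c("lnc_mg_g", "lpc_mg_g", "lcc_mg_g", "sla", "ldmc",
             "lnc_area", "lpc_area")
    trait_names <- intersect(std, names(traits))
  }
  missing_tr <- setdiff(trait_names, names(traits))
  if (length(missing_tr) > 0L)
    stop("trait column(s) not found: ", paste(missing_tr, collapse = ", "))

  report <- list()
  for (kind in names(spectra)) {
    sm <- spectra[[kind]]
    common <- intersect(plant_ids(sm), traits$plant_id)
    if (length(common) == 0L)
      stop("no plant shared between the ", kind, " spectra and the traits")
    X <- sm$values[common, , drop = FALSE]
    tr <- traits[match(common, traits$plant_id), , drop = FALSE]
    for (trait in trait_names) {
      y_raw <- tr[[trait]]
      y <- if (isTRUE(config$log_traits)) log_traits(y_raw, common) else y_raw
      corr <- band_correlations(sm$values[common, , drop = FALSE], y)
      sel <- iterative_band_selection(
        X, y, wavelength = sm$wavelength, nlv_max = config$nlv_max,
        scale = config$scale_bands, alpha = config$alpha,
        max_iterations = config$max_iterations)
      last <- sel$metrics[nrow(sel$metrics), ]
      first <- sel$metrics[1L, ]
      k_sel <- match(sel$nlv, sel$loo$nlv_grid)
      held_out <- sel$loo$predictions[, k_sel]
      report[[paste(trait, kind, sep = ".")]] <- list(
        trait = trait, kind = kind, n = length(common),
        log_transformed = isTRUE(config$log_traits),
        nlv = sel$nlv,
        r2_cal = last$r2_cal, r2_val = last$r2_val,
        rmse_cal = last$rmse_cal, rmse_val = last$rmse_val,
        full_spectrum = list(nlv = first$nlv, r2_val = first$r2_val,
                             rmse_val = first$rmse_val),
        iterations = sel$iterations, stop_reason = sel$stop_reason,
        n_bands_retained = sum(sel$band_mask),
        retained_wavelengths = sel$retained_wavelengths,
        p_values = sel$p_values,
        correlations = corr,
        predictions = data.frame(plant_id = common, observed = y,
                                 predicted = held_out),
        residuals = y - held_out)
    }
  }
  structure(report, class = "run_report")
}

#' Write a run report as JSON
#'
#' The machine-readable per-trait, per-spectrum summary (number of latent
#' variables, calibration/validation accuracy, retained bands, per-band
#' p-values, held-out predictions).
#'
#' @param report a [fit_trait_models()] result.
#' @param path output file.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the spectra and trait tables in the pipeline's delimited layout
#' plus a `truth.json` with the latent constituents, the informative-band
#' mask and the theoretical r-squared.
#'
#' @param dataset a [simulate_leaf_dataset()] result.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(dataset$reflectance, file.path(dir, "reflectance.csv"))
  write_spectra(dataset$transmittance, file.path(dir, "transmittance.csv"))
  write_spectra(dataset$absorbance, file.path(dir, "absorbance.csv"))
  write_traits(dataset$traits, file.path(dir, "traits.csv"))
  truth <- dataset$truth
  truth$constituents <- as.data.frame(truth$constituents)
  truth$config <- unclass(truth$config)
  truth$config$features <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
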