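#' Read and write spectra tables
#'
#' Spectra travel as comma-separated UTF-8 text: first column `plant_id`
#' (optionally followed by a `leaf_id` column for per-leaf tables), remaining
#' column headers the integer wavelengths in nm, one row per plant or leaf.
#'
#' @param path file path.
#' @param kind spectrum kind stored in the returned object.
#' @return `read_spectra()`: a [spectral_matrix()]; for per-leaf tables the
#'   rows are leaves and the attribute `leaf_plant_ids` maps each row to its
#'   plant (row ids are `plant_id.leaf_id`).
#' @export
read_spectra <- function(path, kind = "reflectance") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "plant_id")
    stop("first column of ", path, " must be 'plant_id'")
  has_leaf <- ncol(df) >= 2L && names(df)[2] == "leaf_id"
  meta_cols <- if (has_leaf) 1:2 else 1L
  wl <- suppressWarnings(as.numeric(names(df)[-meta_cols]))
  if (any(is.na(wl)))
    stop("non-numeric wavelength header(s) in ", path)
  values <- as.matrix(df[, -meta_cols, drop = FALSE])
  ids <- if (has_leaf) paste(df$plant_id, df$leaf_id, sep = ".") else df$plant_id
  out <- spectral_matrix(values, wl, kind, plant_ids = ids)
  if (has_leaf) attr(out, "leaf_plant_ids") <- df$plant_id
  out
}

#' @rdname read_spectra
#' @param x a [spectral_matrix()].
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectral_matrix"))
  df <- data.frame(plant_id = plant_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw sphere measurement set
#'
#' Same tabular layout as spectra tables with an extra `signal` column
#' taking values `sample`, `white` and `stray` (one row each per leaf) plus
#' a single `panel` row giving the reference panel's absolute reflectance.
#'
#' @param path file path.
#' @return Named list of [sphere_measurement()] objects, one per plant id.
#' @export
read_sphere_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("plant_id", "signal") %in% names(df)[1:2]))
    stop("first two columns of ", path, " must be 'plant_id' and 'signal'")
  wl <- suppressWarnings(as.numeric(names(df)[-(1:2)]))
  if (any(is.na(wl))) stop("non-numeric wavelength header(s) in ", path)
  panel <- df[df$signal == "panel", -(1:2), drop = FALSE]
  if (nrow(panel) != 1L) stop("expected exactly one 'panel' row in ", path)
  panel <- as.numeric(panel[1, ])
  ids <- unique(df$plant_id[df$signal != "panel"])
  out <- lapply(ids, function(id) {
    rows <- df[df$plant_id == id, , drop = FALSE]
    pick <- function(sig) {
      r <- rows[rows$signal == sig, -(1:2), drop = FALSE]
      if (nrow(r) != 1L)
        stop("plant ", id, " needs exactly one '", sig, "' row in ", path)
      as.numeric(r[1, ])
    }
    sphere_measurement(pick("sample"), pick("white"), pick("stray"),
                       panel, wl)
  })
  names(out) <- ids
  out
}

#' Read and write trait tables
#'
#' Delimited text with headers `plant_id`, `fresh_mass_mg`, `dry_mass_mg`,
#' `leaf_area_mm2`, `lnc_mg_g`, `lpc_mg_g`, `lcc_mg_g`.
#'
#' @param path file path.
#' @return `read_traits()`: a data frame.
#' @export
read_traits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_traits
#' @param traits a trait data frame.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mask calibration file
#'
#' Same layout as spectra tables with a `signal` column taking the values
#' `masked_white`, `masked_black`, `true_white`, `true_black` (one row each).
#'
#' @param path file path.
#' @return A [fit_mask_calibration()] result.
#' @export
read_mask_calibration <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "signal") stop("first column of ", path, " must be 'signal'")
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (any(is.na(wl))) stop("non-numeric wavelength header(s) in ", path)
  pick <- function(sig) {
    r <- df[df$signal == sig, -1, drop = FALSE]
    if (nrow(r) != 1L) stop("expected exactly one '", sig, "' row in ", path)
    as.numeric(r[1, ])
  }
  fit_mask_calibration(pick("masked_white"), pick("masked_black"),
                       pick("true_white"), pick("true_black"), wl)
}
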