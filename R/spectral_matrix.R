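#' Spectral matrix of one spectrum kind
#'
#' Container for a plants-by-wavelengths grid of a single spectrum kind
#' (reflectance, transmittance or absorbance). Values are dimensionless
#' fractions of incident radiation; the wavelength axis is explicit, in nm,
#' and strictly increasing.
#'
#' @param values numeric matrix, one row per plant (or per leaf), one column
#'   per spectral band.
#' @param wavelength numeric vector of band centres in nm, strictly
#'   increasing, finite; length must equal `ncol(values)`.
#' @param kind one of `"reflectance"`, `"transmittance"`, `"absorbance"`.
#' @param plant_ids character vector of row identifiers; defaults to
#'   `rownames(values)`.
#' @return An object of class `spectral_matrix`: a list with elements
#'   `values` (matrix with `plant_ids` as rownames), `wavelength` and `kind`.
#' @examples
#' m <- spectral_matrix(matrix(0.4, 2, 3), 400:402, "reflectance",
#'                      plant_ids = c("a", "b"))
#' wavelengths(m)
#' @export
spectral_matrix <- function(values, wavelength, kind,
                            plant_ids = rownames(values)) {
  kind <- match.arg(kind, c("reflectance", "transmittance", "absorbance"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_wavelength_axis(wavelength)
  if (length(wavelength) != ncol(values))
    stop("length(wavelength) [", length(wavelength),
         "] does not match ncol(values) [", ncol(values), "]")
  if (is.null(plant_ids))
    plant_ids <- sprintf("P%03d", seq_len(nrow(values)))
  if (length(plant_ids) != nrow(values))
    stop("length(plant_ids) does not match nrow(values)")
  if (anyDuplicated(plant_ids))
    stop("duplicated plant_ids: ",
         paste(unique(plant_ids[duplicated(plant_ids)]), collapse = ", "))
  rownames(values) <- plant_ids
  colnames(values) <- as.character(wavelength)
  structure(list(values = values, wavelength = as.numeric(wavelength),
                 kind = kind),
            class = "spectral_matrix")
}

#' Validate a wavelength axis
#'
#' A valid axis is numeric, finite, strictly increasing and non-empty.
#' @param wavelength numeric vector in nm.
#' @return Invisibly, the axis; errors otherwise.
#' @keywords internal
check_wavelength_axis <- function(wavelength) {
  if (length(wavelength) == 0L) stop("empty wavelength axis")
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)))
    stop("wavelength axis must be finite numeric")
  if (any(diff(wavelength) <= 0))
    stop("wavelength axis must be strictly increasing")
  invisible(wavelength)
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix: %s, %d plants x %d bands, %g-%g nm>\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @rdname spectral_matrix
#' @param x a `spectral_matrix`.
#' @export
wavelengths <- function(x) x$wavelength

#' @rdname spectral_matrix
#' @export
plant_ids <- function(x) rownames(x$values)

#' Crop a spectral matrix to a wavelength range
#'
#' Retains the bands with `lo_nm <= wavelength <= hi_nm` (both endpoints
#' inclusive, so a 1-nm grid cropped to 400--1800 nm keeps 1401 bands).
#'
#' @param x a [spectral_matrix()].
#' @param lo_nm,hi_nm range limits in nm, `lo_nm < hi_nm`.
#' @return The cropped `spectral_matrix`.
#' @export
crop_spectra <- function(x, lo_nm, hi_nm) {
  stopifnot(inherits(x, "spectral_matrix"))
  if (!(lo_nm < hi_nm)) stop("lo_nm must be smaller than hi_nm")
  keep <- x$wavelength >= lo_nm & x$wavelength <= hi_nm
  if (!any(keep))
    stop(sprintf("no band inside [%g, %g] nm on an axis spanning %g-%g nm",
                 lo_nm, hi_nm, min(x$wavelength), max(x$wavelength)))
  spectral_matrix(x$values[, keep, drop = FALSE], x$wavelength[keep], x$kind,
                  plant_ids = plant_ids(x))
}

#' Average per-leaf spectra into per-plant spectra
#'
#' Leaves measured for the same plant are combined by the arithmetic mean at
#' every band, giving one spectrum per plant.
#'
#' @param x a `spectral_matrix` whose rows are individual leaves.
#' @param leaf_plant_ids character vector, the plant each leaf row belongs
#'   to; length `nrow(x$values)`.
#' @return A `spectral_matrix` with one row per distinct plant, in order of
#'   first appearance.
#' @export
average_leaves <- function(x, leaf_plant_ids) {
  stopifnot(inherits(x, "spectral_matrix"))
  leaf_plant_ids <- as.character(leaf_plant_ids)
  if (length(leaf_plant_ids) != nrow(x$values))
    stop("leaf_plant_ids must have one entry per leaf row")
  ids <- unique(leaf_plant_ids)
  out <- matrix(NA_real_, length(ids), ncol(x$values))
  for (i in seq_along(ids)) {
    rows <- x$values[leaf_plant_ids == ids[i], , drop = FALSE]
    out[i, ] <- colMeans(rows)
  }
  spectral_matrix(out, x$wavelength, x$kind, plant_ids = ids)
}

#' Derive absorbance from reflectance and transmittance
#'
#' Absorbance is the residual fraction `A = 1 - R - T`, computed on the
#' plants present in both inputs. Plants present in only one input are
#' dropped with a warning listing them. Values outside `[0, 1]` are kept
#' (clamping would distort downstream regression inputs) and flagged in the
#' `out_of_range` attribute.
#'
#' @param r reflectance `spectral_matrix`.
#' @param t transmittance `spectral_matrix` on the same wavelength axis.
#' @return An absorbance `spectral_matrix` over the intersection of plants,
#'   with attributes `dropped` (character vector of plants dropped from
#'   either input) and `out_of_range` (logical matrix flagging A outside
#'   `[0, 1]`).
#' @export
compute_absorbance <- function(r, t) {
  stopifnot(inherits(r, "spectral_matrix"), inherits(t, "spectral_matrix"))
  if (r$kind != "reflectance" || t$kind != "transmittance")
    stop("arguments must be a reflectance and a transmittance matrix")
  if (!isTRUE(all.equal(r$wavelength, t$wavelength)))
    stop("reflectance and transmittance are on different wavelength axes")
  common <- intersect(plant_ids(r), plant_ids(t))
  if (length(common) == 0L)
    stop("no plant occurs in both the reflectance and transmittance inputs")
  dropped <- union(setdiff(plant_ids(r), common), setdiff(plant_ids(t), common))
  if (length(dropped) > 0L)
    warning("plants dropped from the absorbance computation: ",
            paste(dropped, collapse = ", "))
  a <- 1 - r$values[common, , drop = FALSE] - t$values[common, , drop = FALSE]
  out <- spectral_matrix(a, r$wavelength, "absorbance", plant_ids = common)
  oor <- a < 0 | a > 1
  if (any(oor))
    warning(sum(oor), " absorbance value(s) outside [0, 1]; kept and flagged")
  attr(out, "dropped") <- dropped
  attr(out, "out_of_range") <- oor
  out
}
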