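#' Per-band Pearson correlation between a trait and the spectrum
#'
#' Exploratory screening: the Pearson correlation coefficient between the
#' trait values and each individual spectral band. Bands with zero variance
#' get `r = 0` and are flagged.
#'
#' @param x a [spectral_matrix()] (or plain matrix, plants by bands).
#' @param y trait vector with one value per plant, non-constant.
#' @return Data frame with columns `wavelength`, `r` and `zero_variance`.
#' @export
band_correlations <- function(x, y) {
  values <- if (inherits(x, "spectral_matrix")) x$values else as.matrix(x)
  wl <- if (inherits(x, "spectral_matrix")) x$wavelength else seq_len(ncol(values))
  if (nrow(values) != length(y)) stop("trait vector and spectra disagree on plants")
  if (stats::var(y) == 0) stop("degenerate trait: var(y) is zero")
  sds <- apply(values, 2L, stats::sd)
  r <- rep(0, ncol(values))
  ok <- sds > 0
  r[ok] <- drop(stats::cor(values[, ok, drop = FALSE], y))
  data.frame(wavelength = wl, r = r, zero_variance = !ok)
}

#' Correlation-strength label
#'
#' Labels the magnitude of a correlation (or determination) coefficient:
#' strong above 0.7, moderate in (0.5, 0.7], weak at or below 0.5. Negative
#' coefficients are labelled by their absolute value.
#'
#' @param r numeric vector with `|r| <= 1`.
#' @return Factor with levels `weak`, `moderate`, `strong`.
#' @export
strength_label <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must not exceed 1")
  a <- abs(r)
  lab <- ifelse(a > 0.7, "strong", ifelse(a > 0.5, "moderate", "weak"))
  factor(lab, levels = c("weak", "moderate", "strong"))
}

#' Pearson correlation matrix of a trait table
#'
#' @param traits data frame or matrix of numeric trait columns with at least
#'   3 plants; every trait must vary.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
trait_correlation_matrix <- function(traits) {
  m <- as.matrix(traits[vapply(as.data.frame(traits), is.numeric, logical(1))])
  if (nrow(m) < 3L) stop("at least 3 plants are required")
  zero <- apply(m, 2L, stats::sd) == 0
  if (any(zero))
    stop("zero-variance trait(s): ", paste(colnames(m)[zero], collapse = ", "))
  stats::cor(m)
}

#' Variance explained by principal components of the trait table
#'
#' Traits are standardized to unit variance (they carry heterogeneous
#' units), so the decomposition is of the trait correlation matrix. Returns
#' the cumulative fraction of total variance accounted for by the first
#' `1..k` components.
#'
#' @param traits numeric trait table, at least 3 plants.
#' @param k number of leading components (default: all).
#' @return Numeric vector of length `k`, the cumulative variance fractions,
#'   with attribute `eigenvalues` (all eigenvalues, descending).
#' @export
pca_variance_explained <- function(traits, k = NULL) {
  cm <- trait_correlation_matrix(traits)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (is.null(k)) k <- length(ev)
  if (k > length(ev))
    stop("k exceeds the number of traits (", length(ev), ")")
  out <- cumsum(ev)[seq_len(k)] / sum(ev)
  attr(out, "eigenvalues") <- ev
  out
}
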