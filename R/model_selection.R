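#' Leave-one-out validation of a PLSR model
#'
#' Each plant in turn is held out, the model is refitted on the remaining
#' `n - 1` plants, and the held-out plant is predicted at every number of
#' latent variables up to `min(nlv_max, n - 3)`. Validation RMSE and
#' r-squared are computed over the `n` held-out predictions at each size.
#' The regression coefficient vector of every fold model is recorded for
#' the per-band significance test.
#'
#' Folds are deterministic (one per plant); there is no randomness in the
#' validation.
#'
#' @param X numeric matrix, plants by bands.
#' @param y numeric response vector, `length(y) == nrow(X) >= 4`.
#' @param nlv_max cap on the number of latent variables considered; default
#'   `min(nrow(X) - 2, 15, ncol(X))`.
#' @param scale passed to [fit_plsr()].
#' @return An object of class `loo_result`: list with `predictions`
#'   (plants x nlv matrix of held-out predictions), `rmse_val`, `r2_val`
#'   (per nlv), `fold_coefs` (array folds x bands x nlv), `nlv_grid`.
#' @export
loo_validate <- function(X, y, nlv_max = NULL, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 4L) stop("leave-one-out validation requires at least 4 plants")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (is.null(nlv_max)) nlv_max <- min(n - 2L, 15L, p)
  kmax <- min(nlv_max, n - 3L, p)
  if (kmax < 1L) stop("too few plants for any latent variable")
  predictions <- matrix(NA_real_, n, kmax)
  fold_coefs <- array(NA_real_, c(n, p, kmax))
  for (i in seq_len(n)) {
    fit <- fit_plsr(X[-i, , drop = FALSE], y[-i], nlv_max = kmax,
                    scale = scale)
    for (k in seq_len(kmax)) {
      kk <- min(k, fit$nlv)  # fold model may saturate below kmax
      predictions[i, k] <- predict(fit, X[i, ], nlv = kk)
      fold_coefs[i, , k] <- fit$coef[, kk]
    }
  }
  rmse_val <- apply(predictions, 2L, rmse, observed = y)
  r2_val <- apply(predictions, 2L, r_squared, observed = y)
  structure(list(predictions = predictions, rmse_val = rmse_val,
                 r2_val = r2_val, fold_coefs = fold_coefs,
                 nlv_grid = seq_len(kmax), observed = y),
            class = "loo_result")
}

#' Select the number of latent variables
#'
#' The model size minimizing the leave-one-out validation RMSE; ties are
#' broken toward the smaller (more parsimonious) size.
#'
#' @param loo a [loo_validate()] result.
#' @return Integer number of latent variables.
#' @export
select_nlv <- function(loo) {
  stopifnot(inherits(loo, "loo_result"))
  if (length(loo$rmse_val) == 0L) stop("empty validation RMSE sequence")
  loo$nlv_grid[which.min(loo$rmse_val)]
}

#' Per-band significance of fold regression coefficients
#'
#' Tests, per band, whether the mean regression coefficient over the
#' leave-one-out fold models deviates from zero. Because the fold models
#' share all but one plant, their coefficients are not independent
#' replicates; the standard error is therefore the jackknife estimate from
#' the cross-validation segments (Martens & Martens 2000),
#' `se^2 = (m - 1)/m * sum((b_i - mean(b))^2)` over the `m` folds, and the
#' test is a two-sided t-test with `m - 1` degrees of freedom. A band is
#' significant when `p < alpha`. Degenerate bands with zero fold variance
#' get `p = 0` when the mean coefficient is nonzero and `p = 1` when it is
#' zero.
#'
#' @param fold_coefs numeric matrix, folds by bands (at least 3 folds), e.g.
#'   `loo$fold_coefs[, , nlv]`.
#' @param alpha significance threshold (default 0.1).
#' @return List with `p_values` (per band), `t` (per-band statistics) and
#'   `significant` (logical, `p < alpha`).
#' @export
band_significance <- function(fold_coefs, alpha = 0.1) {
  fold_coefs <- as.matrix(fold_coefs)
  m <- nrow(fold_coefs)
  if (m < 3L) stop("at least 3 folds are required")
  mean_b <- colMeans(fold_coefs)
  se <- sqrt((m - 1) / m * colSums(sweep(fold_coefs, 2L, mean_b)^2))
  t_stat <- mean_b / se
  p <- 2 * stats::pt(-abs(t_stat), df = m - 1)
  p[se == 0 & mean_b != 0] <- 0
  p[se == 0 & mean_b == 0] <- 1
  list(p_values = p, t = t_stat, significant = p < alpha)
}

#' Iterative spectral band selection
#'
#' Repeats: (1) leave-one-out validation on the currently retained bands;
#' (2) latent-variable selection by minimum validation RMSE; (3) per-band
#' significance test of the fold coefficients at the selected size
#' ([band_significance()], re-selected each iteration). If every band is
#' significant the loop stops (`all_significant`). If no band is significant
#' all current bands are retained and the loop stops (`none_significant`).
#' Otherwise the predictors are cropped to the significant bands and
#' revalidated; a crop that does not strictly decrease the validation RMSE
#' is discarded and the previous model is returned (`no_improvement`).
#' A hard iteration cap guards against cycling (`max_iterations`).
#'
#' Retained bands are nested across iterations (a band once dropped never
#' returns) and the returned validation RMSE is the minimum over all
#' accepted iterations.
#'
#' Note that the selection and the reported validation metrics use the same
#' leave-one-out predictions, so the post-selection `r2_val`/`rmse_val` are
#' optimistically biased estimates of accuracy on new plants; the
#' first-iteration (full-spectrum) metrics carry no selection bias.
#'
#' @param X numeric matrix, plants by bands.
#' @param y numeric response vector.
#' @param wavelength optional band axis in nm used for reporting; defaults
#'   to column index.
#' @param nlv_max,scale passed to [loo_validate()].
#' @param alpha band-significance threshold (default 0.1).
#' @param max_iterations iteration cap (default 20).
#' @return An object of class `band_selection`: list with `band_mask`
#'   (logical over the original bands), `nlv`, `p_values` (over retained
#'   bands), `metrics` (data frame per accepted iteration: `iteration`,
#'   `n_bands`, `nlv`, `rmse_val`, `r2_val`, `rmse_cal`, `r2_cal`),
#'   `iterations`, `stop_reason`, `fit` (final refit on all plants),
#'   `loo` (final [loo_validate()] result), `wavelength`.
#' @export
iterative_band_selection <- function(X, y, wavelength = NULL, nlv_max = NULL,
                                     scale = FALSE, alpha = 0.1,
                                     max_iterations = 20L) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("X has no bands")
  if (is.null(wavelength)) wavelength <- seq_len(ncol(X))
  mask <- rep(TRUE, ncol(X))
  metrics <- NULL
  best <- NULL
  stop_reason <- "max_iterations"
  for (it in seq_len(max_iterations)) {
    loo <- loo_validate(X[, mask, drop = FALSE], y, nlv_max = nlv_max,
                        scale = scale)
    k <- select_nlv(loo)
    fc <- loo$fold_coefs[, , k, drop = FALSE]
    dim(fc) <- dim(fc)[1:2]
    sig <- band_significance(fc, alpha = alpha)
    if (it > 1L && loo$rmse_val[k] >= best$rmse_val) {
      stop_reason <- "no_improvement"  # discard the crop, keep previous model
      break
    }
    fit <- fit_plsr(X[, mask, drop = FALSE], y, nlv_max = k, scale = scale)
    cal <- fit$fitted[, min(k, fit$nlv)]
    row <- data.frame(iteration = it, n_bands = sum(mask), nlv = k,
                      rmse_val = loo$rmse_val[k], r2_val = loo$r2_val[k],
                      rmse_cal = rmse(y, cal), r2_cal = r_squared(y, cal))
    metrics <- rbind(metrics, row)
    best <- list(mask = mask, nlv = k, p_values = sig$p_values,
                 rmse_val = loo$rmse_val[k], loo = loo, fit = fit)
    if (all(sig$significant)) { stop_reason <- "all_significant"; break }
    if (!any(sig$significant)) { stop_reason <- "none_significant"; break }
    mask[mask] <- sig$significant
  }
  structure(list(band_mask = best$mask, nlv = best$nlv,
                 p_values = best$p_values, metrics = metrics,
                 iterations = nrow(metrics), stop_reason = stop_reason,
                 fit = best$fit, loo = best$loo,
                 wavelength = wavelength,
                 retained_wavelengths = wavelength[best$mask]),
            class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(paste0("<band_selection: %d/%d bands retained, nlv = %d, ",
                     "r2_val = %.3f, rmse_val = %.4g, stop: %s>\n"),
              sum(x$band_mask), length(x$band_mask), x$nlv,
              last$r2_val, last$rmse_val, x$stop_reason))
  invisible(x)
}
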