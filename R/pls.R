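#' Fit a single-response partial least squares regression (NIPALS)
#'
#' Projects the predictor bands onto orthogonal latent variables, each a
#' linear combination of the original bands chosen to maximize covariance
#' with the response, and regresses the response on them. PLSR handles many
#' collinear predictors (e.g. 1401 spectral bands for a few dozen plants)
#' where ordinary least squares is not applicable.
#'
#' Predictors and response are mean-centered; bands are not scaled to unit
#' variance by default because reflectance bands share a common scale
#' (set `scale = TRUE` to standardize). The NIPALS sequence extracts one
#' latent variable at a time: weights from the covariance of the deflated
#' predictors with the deflated response, scores, loadings, then rank-one
#' deflation. With a single response the inner iteration converges in one
#' pass; the loop still checks convergence to the stated tolerance.
#' Extraction stops early when the residual covariance vanishes (predictor
#' rank exhausted), so `nlv` may be smaller than `nlv_max`.
#'
#' Regression coefficients on the original (centered) band scale are stored
#' for every number of components `k <= nlv`; with `k` equal to the rank of
#' the centered predictor matrix they coincide with the ordinary
#' least-squares solution.
#'
#' @param X numeric matrix, plants by bands.
#' @param y numeric response vector, `length(y) == nrow(X) >= 3`,
#'   non-constant.
#' @param nlv_max maximum number of latent variables; default
#'   `min(nrow(X) - 2, 15, ncol(X))`. Must be `<= min(nrow(X) - 1, ncol(X))`.
#' @param scale standardize bands to unit variance before fitting
#'   (default `FALSE`).
#' @param tol convergence tolerance of the inner NIPALS iteration
#'   (default 1e-10).
#' @param max_inner_iter cap on inner iterations per component (default 500).
#' @return An object of class `plsr_fit`: list with `x_mean`, `x_scale`,
#'   `y_mean`, `weights` (bands x nlv), `x_loadings`, `y_loadings`, `scores`
#'   (plants x nlv), `coef` (bands x nlv, original band scale), `nlv`,
#'   `fitted` (plants x nlv).
#' @export
fit_plsr <- function(X, y, nlv_max = NULL, scale = FALSE,
                     tol = 1e-10, max_inner_iter = 500L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 3L) stop("at least 3 observations are required")
  if (stats::var(y) == 0) stop("degenerate response: var(y) is zero")
  if (is.null(nlv_max)) nlv_max <- min(n - 2L, 15L, p)
  nlv_max <- as.integer(nlv_max)
  if (nlv_max < 1L || nlv_max > min(n - 1L, p))
    stop("nlv_max must lie in [1, min(nrow(X) - 1, ncol(X))]")

  x_mean <- colMeans(X)
  x_scale <- rep(1, p)
  Xc <- sweep(X, 2L, x_mean)
  if (scale) {
    x_scale <- apply(Xc, 2L, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2L, x_scale, "/")
  }
  y_mean <- mean(y)
  yc <- y - y_mean

  W <- matrix(0, p, nlv_max); P <- matrix(0, p, nlv_max)
  Tm <- matrix(0, n, nlv_max); Q <- numeric(nlv_max)
  Xr <- Xc; yr <- yc; k <- 0L
  for (a in seq_len(nlv_max)) {
    # with one response the NIPALS inner iteration is exact after a single
    # pass (u = yr is fixed), so no convergence loop is needed; tol and
    # max_inner_iter are kept in the signature for a multi-response extension
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yc^2)))) break
    w <- w / nw
    tvec <- Xr %*% w
    tt <- sum(tvec^2)
    if (tt < 1e-24) break
    pvec <- crossprod(Xr, tvec) / tt
    q <- sum(tvec * yr) / tt
    Xr <- Xr - tcrossprod(tvec, pvec)
    yr <- yr - q * tvec
    k <- a
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- tvec; Q[a] <- q
  }
  if (k == 0L) stop("no latent variable could be extracted (X is constant)")
  W <- W[, seq_len(k), drop = FALSE]; P <- P[, seq_len(k), drop = FALSE]
  Tm <- Tm[, seq_len(k), drop = FALSE]; Q <- Q[seq_len(k)]

  coef <- matrix(0, p, k)
  fitted <- matrix(0, n, k)
  for (a in seq_len(k)) {
    Ra <- W[, seq_len(a), drop = FALSE] %*%
      solve(crossprod(P[, seq_len(a), drop = FALSE],
                      W[, seq_len(a), drop = FALSE]),
            diag(a))
    b <- Ra %*% Q[seq_len(a)]
    coef[, a] <- b / x_scale  # back to the original band scale
    fitted[, a] <- y_mean + Xc %*% b
  }
  dimnames(coef) <- list(colnames(X), NULL)
  structure(list(x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
                 coef = coef, nlv = k, fitted = fitted),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit: %d band(s), %d latent variable(s)>\n",
              nrow(x$coef), x$nlv))
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' `y_mean + (X_new - x_mean) %*% coef[, nlv]`. With `nlv = 0` the null
#' model is used and every prediction equals the training response mean.
#' Requesting more components than the model extracted uses all extracted
#' components (the model is saturated beyond its rank).
#'
#' @param object a [fit_plsr()] result.
#' @param newdata numeric matrix (or vector for a single plant) with the
#'   training band count.
#' @param nlv number of latent variables to use; default all extracted.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_fit <- function(object, newdata, nlv = object$nlv, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " band(s); the model was fitted on ",
         length(object$x_mean))
  if (nlv < 0L) stop("nlv must be >= 0")
  if (nlv == 0L) return(rep(object$y_mean, nrow(newdata)))
  k <- min(nlv, object$nlv)
  drop(object$y_mean +
         sweep(newdata, 2L, object$x_mean) %*% object$coef[, k])
}

#' Coefficient of determination
#'
#' `1 - SS_residual / SS_total`, with the total sum of squares taken about
#' the mean of the observations. The value may be negative: the model's
#' residuals then exceed those of using the mean observation as predictor.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return Scalar r-squared, at most 1, possibly negative.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("at least 2 observations are required")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("var(observed) is zero")
  1 - sum((observed - predicted)^2) / sst
}

#' Root mean square error
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return `sqrt(mean((observed - predicted)^2))`, in response units.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  sqrt(mean((observed - predicted)^2))
}
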