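test_that("noiseless linear signal validates perfectly at one component", {
  set.seed(2)
  x <- rnorm(12)
  X <- cbind(x, rnorm(12) * 0)  # second band constant
  lo <- loo_validate(X, 3 * x, nlv_max = 2)
  expect_gt(lo$r2_val[1], 0.999)
})

test_that("held-out predictions equal explicit per-fold refits", {
  for (n in c(4, 6, 8)) {
    set.seed(n)
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    kmax <- min(15, n - 3, 2)
    lo <- loo_validate(X, y, nlv_max = 15)
    expect_identical(ncol(lo$predictions), as.integer(kmax))
    for (i in seq_len(n)) {
      refit <- fit_plsr(X[-i, , drop = FALSE], y[-i], nlv_max = kmax)
      for (k in seq_len(kmax))
        expect_identical(lo$predictions[i, k],
                         predict(refit, X[i, ], nlv = min(k, refit$nlv)))
    }
  }
})

test_that("at full rank the held-out predictions match a least-squares oracle", {
  set.seed(41)
  n <- 8
  X <- matrix(rnorm(n * 2), n, 2)
  colnames(X) <- c("b1", "b2")
  y <- rnorm(n)
  lo <- loo_validate(X, y, nlv_max = 15)   # kmax = min(15, 5, 2) = 2 = rank
  df <- data.frame(y = y, X)
  oracle <- vapply(seq_len(n), function(i) {
    unname(predict(lm(y ~ b1 + b2, data = df[-i, ]), newdata = df[i, ]))
  }, numeric(1))
  expect_equal(lo$predictions[, 2], oracle, tolerance = 1e-8)
})

test_that("response unrelated to the spectra validates below the mean benchmark", {
  set.seed(99)
  r2 <- replicate(200, {
    X <- matrix(rnorm(12 * 6), 12, 6)
    y <- rnorm(12)
    min_loo <- loo_validate(X, y, nlv_max = 4)
    min_loo$r2_val[which.min(min_loo$rmse_val)]
  })
  expect_lt(median(r2), 0)
})

test_that("loo_validate rejects tiny samples", {
  expect_error(loo_validate(matrix(rnorm(6), 3, 2), rnorm(3)), "at least 4")
})

test_that("select_nlv minimizes validation RMSE with ties toward fewer components", {
  mk <- function(rmse_val) structure(
    list(rmse_val = rmse_val, nlv_grid = seq_along(rmse_val)),
    class = "loo_result")
  expect_identical(select_nlv(mk(c(0.5, 0.3, 0.4))), 2L)
  expect_identical(select_nlv(mk(c(0.5, 0.3, 0.3))), 2L)
  expect_identical(select_nlv(mk(0.7)), 1L)
})

test_that("band significance uses the jackknife fold variance", {
  # constant nonzero coefficient: zero fold variance, significant
  fc <- matrix(0.7, 5, 1)
  s <- band_significance(fc)
  expect_equal(s$p_values, 0)
  # sign-balanced coefficients: zero mean, not significant
  fc <- matrix(c(-0.3, 0.3, -0.3, 0.3), 4, 1)
  expect_false(band_significance(fc)$significant)
  # zero-variance zero-mean band
  expect_equal(band_significance(matrix(0, 4, 1))$p_values, 1)
  # hand-checked t: folds {1.0, 1.2, 0.8, 1.1, 0.9}, mean 1, ss 0.1,
  # se = sqrt(4/5 * 0.1), t = 1/se, p = 2*pt(-t, 4) ~ 0.024 < 0.1
  fc <- matrix(c(1.0, 1.2, 0.8, 1.1, 0.9), 5, 1)
  s <- band_significance(fc, alpha = 0.1)
  expect_equal(s$t, 1 / sqrt(0.08), tolerance = 1e-12)
  expect_equal(s$p_values, 0.02411011, tolerance = 1e-6)
  expect_true(s$significant)
  expect_error(band_significance(matrix(1, 2, 3)), "3 folds")
})

test_that("uniformly strong predictors stop the loop with all bands significant", {
  set.seed(4)
  y <- rnorm(20)
  X <- sapply(1:3, function(i) y + rnorm(20, 0, 0.01))
  sel <- iterative_band_selection(X, y)
  expect_identical(sel$stop_reason, "all_significant")
  expect_true(all(sel$band_mask))
  expect_identical(sel$iterations, 1L)
})

test_that("planted informative bands are retained and masks are nested", {
  pb <- planted_problem(n = 60, p = 200, informative = 1:10, seed = 17)
  sel <- iterative_band_selection(pb$X, pb$y, nlv_max = 15)
  # the informative bands survive the cropping
  expect_gte(sum(sel$band_mask[pb$informative]), 8)
  # validation error never degrades relative to the full spectrum
  expect_lte(sel$metrics$rmse_val[nrow(sel$metrics)], sel$metrics$rmse_val[1])
  # monotone nesting of retained bands
  expect_true(all(diff(sel$metrics$n_bands) <= 0))
  # returned RMSE is the minimum over accepted iterations
  expect_equal(sel$metrics$rmse_val[nrow(sel$metrics)],
               min(sel$metrics$rmse_val))
  # final metrics correspond to the final mask
  expect_identical(sel$metrics$n_bands[nrow(sel$metrics)],
                   sum(sel$band_mask))
})

test_that("a crop that raises validation RMSE is discarded", {
  # strong planted signal: the loop crops at least once and, when it stops
  # on no_improvement, must return the best accepted iteration's model
  found <- FALSE
  for (seed in 1:6) {
    pb <- planted_problem(n = 40, p = 120, informative = 1:6,
                          noise = 0.5, seed = seed)
    sel <- iterative_band_selection(pb$X, pb$y, nlv_max = 10)
    if (sel$stop_reason == "no_improvement") {
      found <- TRUE
      expect_equal(sel$metrics$rmse_val[nrow(sel$metrics)],
                   min(sel$metrics$rmse_val))
      expect_identical(sum(sel$band_mask),
                       sel$metrics$n_bands[nrow(sel$metrics)])
    }
  }
  expect_true(found)
})

test_that("the null-model band filter is reproducible under a fixed seed", {
  run_once <- function() {
    set.seed(123)
    X <- matrix(rnorm(30 * 80), 30, 80)
    y <- sample(rnorm(30))   # permuted response: global null
    lo <- loo_validate(X, y, nlv_max = 5)
    k <- select_nlv(lo)
    fc <- lo$fold_coefs[, , k, drop = FALSE]
    dim(fc) <- dim(fc)[1:2]
    mean(band_significance(fc)$significant)
  }
  frac1 <- run_once()
  frac2 <- run_once()
  expect_identical(frac1, frac2)
})
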