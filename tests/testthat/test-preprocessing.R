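test_that("normalize_reflectance applies stray subtraction and panel scaling", {
  wl <- 400:404
  # sample equals white: reflectance equals the panel's
  m <- sphere_measurement(rep(100, 5), rep(100, 5), rep(0, 5), 0.99, wl)
  expect_equal(normalize_reflectance(m), rep(0.99, 5))
  # sample equals stray: dark leaf
  m <- sphere_measurement(rep(5, 5), rep(100, 5), rep(5, 5), 0.99, wl)
  expect_equal(normalize_reflectance(m), rep(0, 5))
  # hand arithmetic per band
  m <- sphere_measurement(c(10, 20), c(40, 40), c(0, 20), c(1, 1), 400:401)
  expect_equal(normalize_reflectance(m), c(0.25, 0))
})

test_that("normalize_reflectance rejects a degenerate white reference", {
  m <- sphere_measurement(c(10, 20), c(40, 20), c(0, 20), c(1, 1), 400:401)
  expect_error(normalize_reflectance(m), "401")
})

test_that("normalize_reflectance is invariant to common radiance rescaling", {
  wl <- 400:409
  set.seed(42)
  s <- runif(10, 10, 30); w <- runif(10, 50, 80); st <- runif(10, 0, 5)
  base <- normalize_reflectance(sphere_measurement(s, w, st, 0.99, wl))
  for (f in c(0.5, 3, 17)) {
    scaled <- normalize_reflectance(
      sphere_measurement(f * s, f * w, f * st, 0.99, wl))
    expect_equal(scaled, base)
  }
})

test_that("cropping a 350-2500 nm grid to 400-1800 nm keeps 1401 bands", {
  x <- spectral_matrix(matrix(0.5, 1, 2151), 350:2500, "reflectance")
  cropped <- crop_spectra(x, 400, 1800)
  expect_identical(ncol(cropped$values), 1401L)
  expect_equal(range(cropped$wavelength), c(400, 1800))
})

test_that("cropping to the full range is the identity; empty crops error", {
  x <- toy_spectra()
  full <- crop_spectra(x, min(x$wavelength), max(x$wavelength))
  expect_equal(full$values, x$values)
  expect_error(crop_spectra(x, 3000, 3100), "no band")
  expect_error(crop_spectra(x, 500, 400), "smaller")
})

test_that("nested crops compose to the inner crop", {
  x <- spectral_matrix(matrix(runif(800), 1), 1001:1800, "reflectance")
  twice <- crop_spectra(crop_spectra(x, 1100, 1700), 1200, 1500)
  once <- crop_spectra(x, 1200, 1500)
  expect_equal(twice, once)
})

test_that("Savitzky-Golay smoothing preserves polynomials up to its order", {
  wl <- 400:900
  rows <- rbind(rep(0.4, length(wl)),                    # constant
                0.1 + 1e-4 * wl,                          # linear
                2 - 3e-3 * wl + 2e-6 * wl^2)              # quadratic
  x <- spectral_matrix(rows, wl, "reflectance")
  sm <- savgol_smooth(x, order = 2, window_a_nm = 31, window_b_nm = 51,
                      boundary_nm = 800)
  expect_lt(max(abs(sm$values - rows)), 1e-9)  # includes both windows + edges
})

test_that("interior impulse response equals the least-squares kernel", {
  # oracle: quadratic fit over a 5-sample window, evaluated at the centre;
  # kernel = central row of the hat matrix from the 5x3 normal equations
  A <- outer(-2:2, 0:2, "^")
  H <- A %*% solve(crossprod(A), t(A))
  kernel <- H[3, ]
  n <- 21
  imp <- rep(0, n); imp[11] <- 1
  x <- spectral_matrix(matrix(imp, 1), 400 + seq_len(n) - 1, "reflectance")
  sm <- savgol_smooth(x, order = 2, window_a_nm = 5, window_b_nm = 5,
                      boundary_nm = 800)
  expect_equal(unname(drop(sm$values))[9:13], kernel, tolerance = 1e-12)
  expect_equal(unname(drop(sm$values))[c(1:6, 16:21)], rep(0, 12),
               tolerance = 1e-12)
})

test_that("smoothing rejects even windows, bad grids and long windows", {
  x <- toy_spectra(wavelength = 400:430)
  expect_error(savgol_smooth(x, window_a_nm = 30), "even")
  expect_error(savgol_smooth(x, window_a_nm = 51, window_b_nm = 51),
               "exceeds")
  irregular <- spectral_matrix(matrix(0.5, 1, 4), c(400, 401, 403, 404),
                               "reflectance")
  expect_error(savgol_smooth(irregular), "uniform")
  halfstep <- spectral_matrix(matrix(0.5, 1, 41), seq(400, 480, by = 2),
                              "reflectance")
  expect_error(savgol_smooth(halfstep, window_a_nm = 31), "whole number")
})

test_that("average_leaves takes the per-band arithmetic mean per plant", {
  wl <- 400:402
  leaves <- spectral_matrix(rbind(c(0.2, 0.2, 0.2), c(0.4, 0.4, 0.4),
                                  c(0.5, 0.1, 0.3)),
                            wl, "reflectance", plant_ids = c("l1", "l2", "l3"))
  # one leaf per plant: unchanged
  one <- average_leaves(leaves, c("a", "b", "c"))
  expect_equal(unname(one$values), unname(leaves$values))
  # two leaves of one plant average to 0.3
  two <- average_leaves(leaves, c("a", "a", "b"))
  expect_equal(unname(two$values["a", ]), rep(0.3, 3))
  # brute-force mean over 3 leaves
  three <- average_leaves(leaves, c("a", "a", "a"))
  expect_equal(unname(three$values[1, ]), unname(colSums(leaves$values) / 3))
  expect_error(average_leaves(leaves, c("a", "b")), "one entry per leaf")
})

test_that("absorbance is the residual 1 - R - T on the plant intersection", {
  wl <- 400:401
  r <- spectral_matrix(rbind(c(0.3, 0.6), c(0.3, 0.3), c(0.6, 0.5)), wl,
                       "reflectance", plant_ids = c("a", "b", "c"))
  t <- spectral_matrix(rbind(c(0.2, 0.5), c(0.5, 0.6), c(0.1, 0.1)), wl,
                       "transmittance", plant_ids = c("b", "c", "d"))
  expect_warning(expect_warning(a <- compute_absorbance(r, t), "dropped"),
                 "outside")
  expect_identical(plant_ids(a), c("b", "c"))
  expect_setequal(attr(a, "dropped"), c("a", "d"))
  # b: R=(0.3,0.3), T=(0.2,0.5) -> A=(0.5, -0.2) kept and flagged, not clamped
  expect_equal(unname(a$values["b", ]), c(0.5, 0.2))
  expect_equal(unname(a$values["c", ]), c(-0.1, -0.1))
  expect_true(attr(a, "out_of_range")["c", 2])
  expect_false(attr(a, "out_of_range")["b", 1])
})

test_that("R + T + A is conserved to machine precision", {
  ds <- simulate_leaf_dataset(generator_config(n_plants = 15, seed = 3))
  total <- ds$reflectance$values + ds$transmittance$values +
    ds$absorbance$values
  expect_lt(max(abs(total - 1)), 1e-12)
  # and through compute_absorbance
  a <- compute_absorbance(ds$reflectance, ds$transmittance)
  total2 <- ds$reflectance$values + ds$transmittance$values + a$values
  expect_lt(max(abs(total2 - 1)), 1e-12)
})

test_that("compute_absorbance errors on disjoint plants or mismatched axes", {
  r <- toy_spectra(kind = "reflectance")
  t <- toy_spectra(kind = "transmittance")
  t_other <- spectral_matrix(t$values, t$wavelength, "transmittance",
                             plant_ids = c("x", "y", "z"))
  expect_error(compute_absorbance(r, t_other), "no plant")
  t_axis <- spectral_matrix(t$values, t$wavelength + 100, "transmittance",
                            plant_ids = plant_ids(t))
  expect_error(compute_absorbance(r, t_axis), "different wavelength axes")
})

test_that("seam-jump detection flags abrupt detector transitions", {
  wl <- 990:1010
  smooth <- rep(0.5, length(wl))
  jumped <- smooth; jumped[wl >= 1000] <- 0.58   # 0.08 step at 1000 nm
  x <- spectral_matrix(rbind(smooth, jumped), wl, "reflectance",
                       plant_ids = c("ok", "bad"))
  flags <- detect_seam_jumps(x, seam_nm = 1000, threshold = 0.05)
  expect_identical(unname(flags), c(FALSE, TRUE))
})
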