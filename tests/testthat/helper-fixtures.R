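# Small fixtures built in code, shared across test files.

# a tiny spectral matrix on a 1-nm grid
toy_spectra <- function(n_plants = 3, wavelength = 400:420,
                        kind = "reflectance", seed = 1) {
  set.seed(seed)
  values <- matrix(runif(n_plants * length(wavelength), 0.2, 0.6),
                   n_plants, length(wavelength))
  spectral_matrix(values, wavelength, kind,
                  plant_ids = sprintf("P%03d", seq_len(n_plants)))
}

# planted-signal regression problem: iid bands, a few informative
planted_problem <- function(n = 60, p = 200, informative = 1:10,
                            noise = 0.2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[informative] <- 1
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, informative = informative)
}

# valid laboratory trait table
toy_traits <- function() {
  data.frame(plant_id = c("a", "b", "c"),
             fresh_mass_mg = c(125, 120, 80),
             dry_mass_mg = c(25, 30, 25),
             leaf_area_mm2 = c(500, 450, 300),
             lnc_mg_g = c(20, 15, 30),
             lpc_mg_g = c(1.5, 1.2, 1.9),
             lcc_mg_g = c(450, 430, 470),
             stringsAsFactors = FALSE)
}
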