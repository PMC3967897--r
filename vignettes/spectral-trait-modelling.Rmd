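---
title: "Methods: from sphere radiance to trait prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sphere radiance to trait prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraits)
```

`spectraits` implements a leaf-level chemometric workflow: reduce
integrating-sphere measurements to reflectance (R), transmittance (T) and
absorbance (A) spectra, derive leaf functional traits, and calibrate partial
least squares regression (PLSR) models that predict traits from spectra.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data experiments do and do not demonstrate.

## Spectral reduction

A sphere measurement of one leaf consists of the sample radiance, the
radiance of a white reference panel, and a stray-light radiance recorded
with a light trap behind the input port. Absolute reflectance is

$$R(\lambda) = \frac{\text{sample} - \text{stray}}
{\text{white} - \text{stray}} \cdot \rho_{\text{panel}}(\lambda),$$

with $\rho_{\text{panel}}$ the panel's manufacturer-certified absolute
reflectance. The same reduction applies to transmittance. The formula is
invariant to a common rescaling of the three radiances, so integration time
and illumination intensity cancel. A zero denominator at any band aborts
the reduction with the band named: it indicates a broken reference
measurement, not a recoverable condition.

Reduced per-leaf spectra then pass through four steps, in order:

1. **Seam screening.** Instruments covering 350–2500 nm join several
   detectors; calibration drift between sample and reference measurements
   shows up as an abrupt step exactly at the detector transitions. A leaf
   spectrum is excluded when its first difference at a configured seam
   wavelength (defaults 1000 and 1800 nm) exceeds 0.05 reflectance units.
2. **Cropping** to 400–1800 nm, inclusive on both ends: on the instrument's
   1-nm resampled grid this retains exactly 1401 bands. Outside this range
   the signal-to-noise ratio of the sphere setup is too low to be useful.
3. **Savitzky–Golay smoothing**, second order, with a 31-nm window for
   bands up to 800 nm and a 51-nm window above. Both filters are run over
   the full spectrum and the outputs stitched at the boundary, which avoids
   edge artifacts at the seam itself. Windows are quoted in nm and
   converted to odd sample counts on the uniform grid; non-uniform axes are
   rejected rather than silently resampled. Spectrum ends are fitted by a
   least-squares polynomial over the leading/trailing window, so any
   polynomial up to the filter order passes through unchanged — the
   filter's defining property, and the package's regression test for it.
4. **Per-plant averaging** of the 1–4 leaves measured per plant.

Absorbance is closed as $A = 1 - R - T$ on the plants present in both the R
and T sets; dropped plants are reported. Values outside $[0,1]$ (possible
after noise or mask correction) are flagged but **not clamped**: clamping
would silently distort the regression inputs, and the flags make the
affected plants auditable.

### Mask correction for small-width leaves

Leaves narrower than the sphere port are measured behind a slit mask. The
mask's spectral contribution is removed by a per-band affine inversion
fitted to a white and a black reference measured both masked and unmasked:

$$g(\lambda) = \frac{w_{\text{true}} - b_{\text{true}}}
{w_{\text{masked}} - b_{\text{masked}}}, \qquad
o(\lambda) = w_{\text{true}} - g\,w_{\text{masked}},$$

after which $\hat r = g\,m + o$. This two-point construction maps both
references exactly onto their true spectra, is monotone whenever the
references are ordered consistently, and round-trips any affine
contamination to machine precision — the property the test suite asserts.
The published protocol cites a reference-material correction without
reproducing its formula; the affine inversion is this package's
reconstruction, documented as such. Dual-background transmittance
measurements of narrow leaves reuse the same machinery; since no paired
standard/masked transmittance data exist for validation, that path is
validated synthetically only.

## Traits

From fresh mass, dry mass and leaf area: SLA = area/dry mass (mm²/mg),
LDMC = 1000·dry/fresh (mg/g, the complement of leaf water content), and the
area-based nutrient contents LNC_area = LNC/SLA and LPC_area = LPC/SLA —
with these units the quotient is numerically g/m². The N:P ratio classifies
nutrient limitation: N-limited below 14, P-limited above 16, colimited in
between; the boundary values belong to the colimited class because the
limited classes are defined by strict inequalities. Trait distributions are
right-skewed, so models are fitted on log₁₀(trait); the base is a
convention only (it rescales coefficients and RMSE by a constant and leaves
r² and band selection unchanged).

## PLSR, validation and band selection

The regression core is single-response NIPALS PLSR. Bands are mean-centered
but not variance-scaled by default: reflectance bands share one physical
scale, and scaling would inflate the leverage of low-variance noise bands
(a `scale` switch exists for responses on heterogeneous predictor sets).
With one response the NIPALS weight vector is exact in a single pass per
component, so no inner iteration is needed; extraction stops early if the
predictor residual is exhausted. Coefficients are stored for every model
size, and at full rank they coincide with ordinary least squares — one of
the package's oracle tests, alongside prediction agreement (≤ 1e-6) with an
independent PLSR implementation (`mixOmics`).

Model size is selected by leave-one-out validation: the RMSE of the n
held-out predictions, minimized over the number of latent variables, ties
broken toward the smaller model. Folds are deterministic; the cap is
`min(n_train − 2, 15)` components, generous enough for the single-digit
optima typical of leaf spectra.

**Band significance.** For each band, the regression coefficients of the n
fold models are tested against zero. Fold models share $n-1$ plants, so
fold-to-fold scatter understates the sampling variance of the coefficient
by a factor of about $n$; a plain one-sample t-test on fold coefficients is
therefore degenerate (essentially every band tests significant regardless
of signal). The package uses the jackknife variance estimate for
cross-validation segments (Martens & Martens 2000),
$\widehat{\mathrm{var}}(b) = \frac{m-1}{m}\sum_i (b_i - \bar b)^2$,
with a two-sided t-test on $m-1$ degrees of freedom — the test implemented
by the standard chemometrics software for exactly this situation. Bands
with zero fold variance are significant iff their mean coefficient is
nonzero. No multiple-testing correction is applied, matching the published
procedure; at the default α = 0.1 roughly a tenth of truly uninformative
bands survive each iteration.

**Iterative cropping.** The loop validates, selects the model size,
re-tests the bands at that size (the size may change between iterations),
and refits on the significant bands. It stops when all bands are
significant, when no band is (all bands retained — the documented outcome
for traits with no spectral signal), when a crop fails to *strictly*
decrease the validation RMSE (the crop is discarded and the previous model
returned; non-strict improvement would cycle on plateaus), or at a hard cap
of 20 iterations. Retained bands are nested across iterations and the
returned RMSE is the minimum over accepted iterations.

**A caveat the user should know.** The selection loop reuses the same
leave-one-out predictions that it reports: post-selection r²_val and
RMSE_val are therefore optimistically biased — the loop keeps whatever
bands happen to validate well on these n plants, including some that carry
only noise. The first-iteration (full-spectrum) metrics, which the run
report exposes alongside the final ones under `full_spectrum`, carry no
selection bias and are the honest accuracy estimate. The synthetic
experiments below quantify the gap.

## The synthetic generator

No field dataset is distributed with this workflow, so the generator
emulates the statistical structure the analysis assumes, with an analytic
ground truth instead of a physical radiative-transfer model (PROSPECT-style
simulation is out of scope; Gaussian features keep the truth exact and the
tests fast). Per plant, standard-normal constituent levels $z$ scale
Gaussian absorption features on a red-edge-shaped baseline:

* chlorophyll/pigment: 680 nm, width 40 nm, depth 0.06;
* water: 1200 nm / 50 nm / 0.06 and 1450 nm / 60 nm / 0.12;
* dry matter: 1700 nm / 80 nm / 0.08;

each feature absorbing $\text{depth}\cdot(1 + 0.3 z)$ of its Gaussian, plus
additive noise (default sd 0.005 reflectance units). Transmittance uses 0.8
times the reflectance depths with independent noise and is rescaled so
$R + T \le 1$; absorbance closes the budget exactly. Configurations whose
noiseless spectra leave $[0,1]$ are rejected.

The key knob is the **coupling** $\rho \in [0,1]$ between a measured trait
and its spectrally active constituent:
$\text{trait} = \rho z + \sqrt{1-\rho^2}\,\varepsilon$, rescaled into a
plausible positive range. N content couples to the pigment constituent
(mean 20, sd 2 mg/g), dry matter content to the dry-matter constituent
(realized through the fresh/dry-mass columns, mean 250, sd 40 mg/g);
P and C content are uncoupled. The small coefficients of variation keep the
log transform nearly linear, so the attainable validation r² is $\rho^2$ —
this is the generator's formalization of why a trait can be poorly
predicted even by noise-free spectra: the spectrally relevant fraction of
the trait (e.g. the chlorophyll fraction of total leaf N under varying
light regimes) is not constant across plants.

Defaults are n = 60 plants, noise sd 0.005, ρ = 0.9, on the 400–1800 nm
1-nm axis. What the generator does **not** emulate: band-to-band correlated
instrument noise, multiplicative brightness variation between leaves,
scattering-driven baseline shifts, and the biochemical covariance structure
of real leaves. Passing recovery tests on this generator therefore
demonstrates the correctness of the estimation machinery under the model's
own assumptions, not field-level accuracy.

## Seeded experiments

Three experiments, run by both the test suite and `scripts/acceptance.R`
(the problem sizes are chosen to make each run in seconds on one core):

* **Parameter recovery.** At n = 60, noise 0.005, ρ = 0.9, the median
  full-spectrum LOO r²_val over 10 replicates sits within 0.1 of
  ρ² = 0.81. The post-selection r²_val does not (it lands near 0.95):
  selection optimism, not better prediction.
* **Decoupling monotonicity.** Median r²_val decreases strictly over
  ρ ∈ {1.0, 0.8, 0.6, 0.4, 0.2} (7 replicates each) — the computational
  restatement of trait–constituent decoupling as the mechanism behind poor
  nutrient-trait prediction.
* **Band-selection localization.** With all four features tied to a single
  informative constituent (ρ = 0.95), the median fraction of finally
  retained bands within two feature widths of a planted feature reaches
  80% over the seeded replicates; the final validation RMSE never exceeds
  the initial one and masks are nested. The localization fraction varies
  considerably across realizations (roughly 0.6–0.9) because the stopping
  iteration is data-dependent: an early `no_improvement` stop freezes the
  previous, wider mask together with its surviving false retentions.
  With a single narrow feature on a short axis, localization is weaker
  (~60–70%): at α = 0.1 the ~10% false retentions per iteration dominate
  when the informative window is a small fraction of the axis and the loop
  stops early on `no_improvement`. This sensitivity to the
  informative-to-null band ratio is a property of the published selection
  procedure worth knowing before interpreting retained-band maps.

## Degenerate inputs and numerical conventions

Zero reference denominators, degenerate (constant) responses, zero-variance
traits and empty crop ranges raise errors naming the offending band, plant
or trait. Zero-variance spectral bands get correlation 0 (flagged) in the
screening profile and p = 1 (mean zero) or p = 0 (mean nonzero) in the band
test. r² is always computed against the observed mean, so validation r² can
be negative; RMSE ties in model-size selection resolve to fewer components;
trait PCA operates on the correlation matrix because traits carry
heterogeneous units. All simulations take one explicit integer seed; there
is no hidden global randomness.
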