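---
title: "NIRS hay calibration: models, preprocessing and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIRS hay calibration: models, preprocessing and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haycal)
```

## The problem

Near-infrared reflectance spectroscopy (NIRS) predicts forage nutritive
value — dry matter (DM), crude protein (CP), neutral and acid detergent
fiber (NDF, ADF) and in vitro dry matter digestibility (IVDMD) — from
diffuse reflectance spectra, replacing slow wet-chemistry assays once a
calibration has been built against a reference population. `haycal`
implements the full calibration workflow used by commercial NIRS software
for hay analysis, plus a synthetic-data generator so that every stage can be
exercised, and the effect of sample preparation (grinding to 1 mm versus
scanning coarse, unground material) studied, without access to a
spectrometer.

Spectra live on a 680–2,500 nm grid at 2 nm intervals (911 channels) and
are modelled as absorbance, log(1/R). Reference chemistry is carried in
g/kg (DM as-is, other analytes on a dry-matter basis) and converted to
percent — a factor of exactly 10 — for modelling and reporting, which is
the scale on which SE-type statistics are conventionally quoted.

## Preprocessing ("math treatments")

Four composable operators, applied in a fixed order by `apply_treatment()`:

1. **log(1/R)** (`absorbance_transform()`). Base 10 by default; the
   "log 1/R" phrase is used loosely across the NIRS literature for either
   base, and the choice only rescales the regression coefficients, so we
   default to the dominant convention and expose `base = "natural"`.
2. **SNV** (`snv()`): per-spectrum centering and scaling to unit sample SD
   (denominator n − 1). Removes per-sample multiplicative scatter and
   offsets. Constant spectra are a hard error rather than a silent NaN.
3. **Detrend** (`detrend()`): residual of a least-squares polynomial
   baseline (default order 2) fit against wavelength. Computed with an
   orthonormalized basis on a [−1, 1] rescaled abscissa, so the projection
   is numerically exact and idempotent. The SNV-then-detrend order is the
   standard "SNV-D" convention; both the order and the polynomial order are
   configurable because vendor software does not document its choice.
4. **Gap-segment derivative** (`gap_derivative()`): boxcar smoothing of
   width *s* followed by *d* applications of the gap difference
   f(i + ceil(g/2)) − f(i − floor(g/2)). Margins consumed by the windows are
   dropped — no padding, so no fabricated boundary values reach the model —
   and the wavelength bookkeeping follows the surviving channel centres.
   The floor/ceil split keeps even gaps symmetric.

A treatment code such as `"3,16,16"` reads (derivative order, gap,
smoothing), the convention used in calibration-software reports; a fourth
number (second smoothing pass) is accepted and defaults to off. The default
search grid is the 12 codes {1,2,3,4} × {(4,4), (8,8), (16,16)} with
SNV + detrend, exposed by `default_treatments()`.

## PLS regression and factor selection

`nipals_pls()` implements PLS1 NIPALS: factors are extracted in order of
covariance with the response, the predictor block is deflated after each
factor, and the coefficient path B(k) = W(P'W)⁻¹q is assembled for every
factor count in one fit. Centering only (no autoscaling) is the default for
absorbance spectra; `scale = TRUE` is available. The inner loop guards
degenerate cases with a 1e-10 tolerance and 500-iteration cap, though PLS1
converges in a single pass. Requests beyond the achievable rank truncate
with a warning.

The factor count is chosen by cross-validation (`select_factors()`,
`cv_spec()`): the count, up to the conventional cap of 16, minimizing SECV,
with ties broken toward fewer factors. The default scheme is 10-fold CV
with a seeded shuffle; leave-one-out is available. The scheme matters —
SECV is not comparable across schemes — so it is recorded in every result
and report.

Conventions for the error statistics, chosen to match NIRS practice and
documented so users can recompute under other conventions:

* SEC (calibration) uses denominator n − k − 1, k = PLS factors;
* SECV is the root mean square of pooled out-of-fold residuals
  (denominator n);
* R² (calibration and cross-validation) is 1 − SSE/SST about the observed
  mean, reported unclamped (a warning flags negative values);
* RPD = SD(reference values of the selected samples) / SECV. The
  selected-set SD is the default because published RPD tables are
  consistent with post-screening populations; `rpd_sd = "full"` switches to
  the full-set SD.

## Outlier screening

Spectral outliers use the GH (global H) statistic: squared Mahalanobis
distance of a sample's factor scores from the score centroid, divided by
the number of factors k (`gh_distance()`). The division by k is what makes
the conventional cutoff of 3.0 meaningful in any dimension — the set mean
of GH is (n − 1)/n ≈ 1, and under Gaussian scores GH is roughly χ²(k)/k, so
GH > 3 flags a stable small tail regardless of k; a cutoff of 3.0 on the
raw distance D would flag essentially nothing in high-dimensional score
spaces. Screening runs up to two rounds (gross outliers inflate the
covariance that shields milder ones), with scores from PLS when a response
is available and PCA otherwise.

Laboratory outliers use the t-statistic |predicted − observed| / SEC with a
strict cutoff of 2.5 (`screen_lab()`), applied after an initial calibration
and followed by one refit. Vendor software does not document whether SEC is
recomputed before or after removal; we recompute after each round and keep
both counts in the result's provenance.

The workflow order in `cross_validate()` is: spectral screen → initial
calibration (factor selection by CV) → lab screen → final calibration and
cross-validation on the selected set.

## The synthetic generator

`simulate_hay()` builds datasets with the statistical structure the
workflow assumes, in four layers:

1. **Chemistry.** Analyte values are drawn from truncated normals with the
   alfalfa/timothy population means, SDs and min–max ranges built into
   `hay_population()`; CP is generated as a latent nitrogen draw times
   6.25, mirroring how the laboratory value is defined.
2. **Clean spectra.** Absorbance is a smooth baseline plus a linear
   Gaussian-band mixture of the analyte mass fractions
   (`default_band_library()`): water bands near 1,450/1,940 nm drive DM
   through its moisture complement, protein N–H bands sit near
   1,510/2,054/2,180 nm, carbohydrate/cellulose bands near 1,200/2,270 nm
   and neighbours. Band positions cover the absorption regions commonly
   reported for hay; loadings are realism choices, not measurements. Before
   distortion, absorbance is exactly affine in the concentrations.
3. **Scatter distortion** (per sample): multiply by
   (1 + a + g(λ)) and add b + c·t(λ), with t(λ) the wavelength rescaled to
   [−0.5, 0.5] and g(λ) a smooth random gain field (four broad Gaussian
   bumps with per-sample coefficients). The flat multiplicative a, offset
   b and linear tilt c are the textbook scatter components — and are
   exactly what SNV + detrend removes. The wavelength-dependent gain g is
   the component that *survives* scatter correction; physically it stands
   for the wavelength dependence of the effective path length in
   coarse-particle scattering. A `presentation` component additionally
   jitters the composition seen by the beam relative to the laboratory
   aliquot (in fractions of each analyte's population SD): with intact
   10 cm stems the scanned portion is simply not the milled portion that
   was assayed, and no amount of preprocessing can recover information that
   never reached the detector. Grinding homogenizes, so the ground default
   is near zero.
4. **Channel noise**: i.i.d. Gaussian, SD 0.001 absorbance by default.

Default magnitudes (`default_scatter()`): ground
(mult 0.02, add 0.01, tilt 0.01, mult_tilt 0.01, presentation 0.05);
unground (0.08, 0.05, 0.05, 0.15, 0.55). The flat/offset components follow
the 2%/8% and 0.01/0.05 conventions for ground versus unground scatter; the
gain-field and presentation magnitudes were set so that default pipelines
land in the qualitative regime reported for real hay — ground calibrations
mostly usable (CP strongly so), unground calibrations mostly failing the
acceptance rules — and are plainly labelled tunable conventions, not
fitted quantities. At these defaults a 200-sample ground dataset yields
cross-validated R² around 0.95 for CP and 0.6–0.95 across analytes, and the
paired unground arm drops to roughly 0.4–0.7.

`paired_prep_states()` shares the chemistry, clean spectra and every random
innovation between the two arms, scaling only the distortion magnitudes, so
the preparation contrast is isolated exactly; equalizing the magnitudes
makes the arms identical. Sample IDs name the physical sample, not the
scan, so the arms align by ID.

What the generator does **not** emulate: radiative-transfer physics of
diffuse reflectance, moisture–band interaction chemistry,
instrument-specific noise spectra, correlated analyte populations (draws
are independent, truncated to the observed ranges), or wavelength
registration errors. Passing simulation tests therefore demonstrates that
the workflow is implemented correctly and behaves as expected under its own
assumptions — not that any particular accuracy will be attained on real
hay.

## Acceptance rules and reporting

`acceptance_check()` applies the conventional usability rule: R² of
cross-validation strictly above 0.80 and RPD strictly above 2; it also
monitors SECV/SEC (default warning ratio 1.3) since a cross-validation
error far above the calibration error signals overfitting.
`nirs_calibrate()` grid-searches the 12 treatments by minimum SECV (ties:
higher R²cv, then lower derivative order), and `calibration_table()` /
`write_report()` render the conventional report (treatment, selected n, PLS
terms, R², SE, cross-validation R², SE, RPD; 2 decimals for display, full
precision in machine-readable output). `write_model()` serializes a fitted
calibration — treatment, grid, centering, regression vector — as JSON for
standalone prediction with `read_model()`.

## Numerical and design notes

* Fold assignment, and every other random choice, is controlled by explicit
  seeds; the caller's RNG state is saved and restored, and identical
  configuration yields byte-identical machine-readable outputs (timestamps
  are confined to one report header line that can be disabled).
* A fold whose training half has zero response variance triggers one
  reshuffle, then a hard error.
* Problem sizes in the test-suite simulations (up to n = 200 samples,
  10 seeds for the preparation contrast) were chosen as the smallest at
  which the population statistics and the contrast are stable; larger runs
  only tighten the Monte-Carlo error.
* Non-default wavelength grids are accepted everywhere with a warning;
  resampling between grids is deliberately out of scope, as are MSC,
  Savitzky–Golay derivatives, PLS2, and robust covariance estimates for the
  GH screen.
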