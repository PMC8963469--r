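---
title: "Methods: multi-temporal SPAD retrieval from hyperspectral reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-temporal SPAD retrieval from hyperspectral reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chlorospec)
```

## The problem

SPAD meters give a unitless, transmittance-based proxy for leaf chlorophyll
(0--70 under field conditions) but only where a person can clip a leaflet.
Hyperspectral cameras on low-flying platforms observe every plant of a
field at millimetre ground sampling distance across 400--1,000 nm. This
package implements a machine-learning workflow that links the two: leaf
level spectra paired with SPAD readings train regression models which are
then applied per pixel to calibrated reflectance data-cubes, turning five
field campaigns over a growing cycle into multi-temporal SPAD maps with
per-pixel uncertainty where the model supports it.

Because the workflow must be testable without access to field data, a
first-class synthetic module (`simulateSpad()`, `simulateLeafSpectrum()`,
`simulateCube()`) generates study-shaped data: every downstream stage is
exercised against ground truth the generator knows exactly.

## The synthetic study conditions

The generator reproduces the structure of a five-campaign phenotyping
trial on a 60 x 20 plant grid in four plots of 300 plants:

* **SPAD distributions.** Each campaign carries a five-number summary
  (min, Q1, median, Q3, max); campaigns rise across the season from a
  median of 33 (Q1 29, Q3 38) at establishment to a median of 55 before
  harvest, with 108 leaflet samples per campaign and 75 in the last
  (plant losses before the final collection). Draws come from the
  piecewise-uniform law whose CDF interpolates the five-number summary.
  We chose this law over a moment-matched Beta because it reproduces the
  box-plot summaries *exactly* and has positive density at the support
  edges, so empirical extremes converge at rate 1/n; a Beta with interior
  mass converges too slowly at the whiskers for distributional tests at
  n = 10^4. Whisker ends not reported for a campaign are fixed plausible
  values, declared once in `defaultCampaigns()`.
* **Leaf spectra.** A Beer--Lambert construction on the 1-nm grid:
  a NIR plateau drawn from the campaign's NIR statistics, attenuated by
  `exp(-k(lambda) * c(SPAD))` with Gaussian absorber components at the
  chlorophyll-a (430, 680 nm) and chlorophyll-b (460, 650 nm) features, a
  calibrated baseline visible absorption (0.366, set so the first
  campaign's ensemble green peak averages 0.18 against a 0.49 NIR
  plateau), and an exponential SPAD link `c(s) = exp(s/25) - 1`
  reflecting the mostly exponential SPAD-to-chlorophyll relations
  reported for many species. A logistic switch centred at 715 nm closes
  pigment absorption through the red edge, so the inflection point moves
  to longer wavelengths as SPAD rises — the red-edge behaviour the
  narrowband indices rely on. Reflectance at 680 nm is strictly
  decreasing in SPAD.
* **Campaign drift.** Each campaign multiplies the SPAD link by
  `(1 + drift)` with the default progressive trend (0, 0.15, 0.30, 0.45,
  0.60). The trend emulates the structural and physiological changes that
  move the SPAD-to-spectrum mapping across growth stages. It is
  deliberately *trending*, not i.i.d.: a workflow-level comparison of
  learning strategies needs non-stationarity with a direction, because a
  random per-campaign perturbation gives a moving training window no
  recency advantage by construction. `defaultCampaigns(drift = FALSE)`
  is the stationary control.
* **Scenes.** `simulateCube()` renders the plant grid at 0.007 m GSD
  (3 x 3 pixels per plant in the mini layout used throughout the tests:
  12 x 5 plants, which keeps a full pipeline run under a minute), a
  sandy-loam soil background, six flat gray calibration panels
  (reflectances 0.03--0.56), an exact plant-id mask, and an optional
  radiance mode that inverts a known per-band affine calibration so the
  empirical-line fit can be validated by round trip.

What the generator does *not* emulate: radiative-transfer realism
(PROSPECT-style biochemistry), canopy geometry and BRDF, shadows,
mixed soil-leaf pixels at plant borders, and sensor effects beyond
additive Gaussian noise and a brightness jitter. Tests passing on this
synthetic world therefore validate the *workflow machinery* — resampling,
calibration, index algebra, strategy logic, importance consensus, map
aggregation — not the field-data accuracies of any real campaign.

## Preprocessing chain

1. **Gaussian spectral-response resampling** (`gaussianResample()`): each
   of the 272 bands (400--1,000 nm, 6 nm FWHM) is a normalised
   Gaussian-weighted average of 1-nm samples with sigma = FWHM/2.3548,
   truncated at +-3 sigma and renormalised; inputs from full-range field
   spectroradiometers are cropped to the sensor span first. The operator
   is linear and exactly preserves constants.
2. **Empirical line** (`empiricalLineFit()`, `applyEmpiricalLine()`):
   per-band ordinary least squares of known panel reflectance on observed
   panel radiance; exact on affine data, with rank-deficiency detection
   per band. Results outside [0, 1] are clipped and counted.
3. **Savitzky--Golay smoothing** (`savgolSmooth()`, `smoothCube()`):
   window of 11 bands, polynomial order 2 by default (the source study
   states no values; these are conventional for 272-band spectra and are
   configurable). Endpoints use one-sided least-squares polynomial fits,
   which keep polynomials of the filter order exact everywhere — mirror
   padding would not.
4. **Minimum noise fraction** (`mnfDenoise()`): noise covariance from
   horizontal 1-pixel shift differences (within the plant mask when
   given, avoiding soil/plant edges), noise-whitened eigendecomposition,
   reconstruction from the leading components. Full rank is an
   isomorphism; when `k` is not given, components with noise-whitened
   eigenvalue above 1 are kept. A singular noise covariance triggers a
   warned ridge regularisation; an exactly zero noise estimate returns
   the cube unchanged with a warning.

## The vegetation-index registry

Sixty pigment-oriented indices in nine groups (broadband and narrowband
greenness, light-use efficiency, senescence, stress-on-pigments, water
content, reflectance-based and derivative-based leaf chlorophyll,
continuum-removed), each a pure function of a band sampler with
nearest-band snapping (no interpolation — discrete-band instrument
practice). Derivatives are Savitzky--Golay first derivatives in per-nm
units with the preprocessing defaults; continuum removal divides by the
upper convex hull over the 520--750 nm chlorophyll feature (plus a
955--985 nm hull for the water-band depth); red-edge position is
available as the maximum first derivative in 680--760 nm or the
four-point interpolation formula. On the default grid the registry
references exactly 145 unique band centers; `registryWavelengths()`
defines the 145-band "selected bands" predictor set as the exact column
subset of the all-bands matrix. Roughly half the registry is named
directly in the chlorophyll-VI literature; the remaining slots are
reconstructions from the same families and say so in their citation
field.

A note on grid robustness: indices built from plateau or broad-feature
samples agree between a 1-nm computation and the 272-band computation to
well under 2%. Indices that ratio small reflectance differences on the
steep red-edge transition, or ratio first derivatives, are *inherently*
scale-dependent — a 6 nm response function smooths 1-nm structure — and
can differ by tens of percent between grids. This is instrument physics,
not a defect; the workflow therefore computes all indices on the sensor
grid, and the test suite asserts the 2% agreement only for the 35
broad-feature indices.

## Learning harness

`makeDataset()` assembles one of three predictor sets (272 bands, the
145 selected bands, 60 VIs) against SPAD responses with ordered campaign
labels. `splitDataset()` performs the distribution-matched 80/20 split:
within each campaign, samples are ranked by SPAD, dealt into
`round(0.2 n)` rank groups, and one member per group drawn into
validation — a 108-sample campaign gives 86/22.

The roster (`rosterConfigs()`) holds 17 configurations: multivariate
linear; PLSR; fine/medium/coarse trees (minimum leaf sizes 4/12/36);
boosted and bagged ensembles of 60 medium trees; SVR with linear,
quadratic, cubic and fine/medium/coarse Gaussian kernels (kernel scales
sqrt(p)/4, sqrt(p), 4 sqrt(p)); GPR with exponential,
squared-exponential, Matern-5/2 and rational-quadratic kernels. Standard
estimators back the tree, forest, boosting and SVR families. PLSR is an
in-package NIPALS implementation (autoscaled predictors; component count
tuned by 5-fold cross-validated RMSE over 1..15) whose predictions are
test-verified against an independent PLS implementation; the weights are
retained per component for the importance analysis. GPR is an in-package
exact implementation — Cholesky solves, marginal-likelihood
hyperparameter tuning with analytic gradients for the
squared-exponential kernel, predictive variance, and optional ARD — again
cross-checked against an independent implementation at pinned
hyperparameters.

**Strategies.** Sequential learning fits one model on all campaigns
pooled. Retraining refits as campaigns arrive on training sets that
track the crop's current state — campaign 1 alone, then the current and
previous campaign together (t1; t1+t2; t2+t3; t3+t4; t4+t5) — with
hyperparameters tuned on the first campaign and frozen afterwards, so
the model architecture is kept while the data window moves. Campaign i
is predicted by model i. With a single campaign the two strategies are
identical by construction.

**Metrics and selection.** R² uses the conventional mean-based
denominator (the alternative with predictions in the denominator that
sometimes appears in print is treated as a typographical variant); RMSE
and MAE are in SPAD units. `selectModels()` keeps configurations with
validation RMSE and MAE both at or below 5 SPAD units — the combined
meter accuracy (±1) and the 2--4 unit environmental biases a SPAD
reading carries. `compareDistributions()` adds the per-campaign
five-number comparison of retrieved versus observed validation
distributions that guards against models that score well but flatten the
temporal dynamics.

The strategy experiment (`strategyExperiment()`) uses PLSR by default:
it is the fastest roster member that both shows the drift effect and
passes the stationary control cleanly. Random forest shows the
retraining advantage even more strongly, but its moving window trains on
less data than the pooled model, which a paired test detects as a small
systematic penalty under stationarity — a data-size artefact, not a
strategy effect.

## Importance consensus

Three relevance mechanisms are extracted from their native fits: PLSR
weight vectors per component, aggregated per predictor as the maximum
absolute weight across components (a predictor relevant in *any*
component stays relevant; the per-component vectors remain available);
random-forest impurity importance normalised to sum one; and the ARD
length scales of a squared-exponential GP refitted with one scale per
predictor — the "weakness index", large scale meaning weak predictor.
Prediction runs may use isotropic kernels; the importance run refits
with ARD on standardized inputs so scales are comparable. Quartile
classification (linear-interpolation quantiles, inclusive comparisons)
keeps scores at or above Q3 for PLSR and the forest and at or below Q1
for the GP weakness — Q1 uniformly, resolving an internal labelling
inconsistency in the source material in favour of its own text.
`importanceConsensus()` counts how many methods flag each predictor
(1--3) and `mergeBandRanges()` reports contiguous relevant bands within
10 nm as a single variable at their central wavelength.

## Mapping

`predictCube()` applies a fitted model to every masked-in pixel of a
reflectance or VI cube. Retrievals outside the meter's 0--70 operating
range become nodata gap pixels and are counted — not clipped — mirroring
how negative retrievals appear as gaps in published map series. GPR maps
carry a sigma95 layer: 1.96 times the predictive standard deviation, the
half-width of the central 95% interval of the Gaussian predictive law
(the reading of "standard deviation at 95% confidence" adopted here; the
plain-SD reading is a factor 1.96 away and available from
`predictSpad(se = TRUE)`). `plantAverage()` aggregates valid pixels to
the rows x columns sowing matrix, with empty-cell counts and mean
sigma95 attached; no brightness or shadow filter is applied before
averaging, since none is specified for the reference workflow.

A mapping subtlety the tests document: under campaign drift a
sequentially trained model predicts a single-campaign scene with a bias
of several SPAD units (it learned the average mapping across drifted
campaigns), so scenes are mapped by the retraining model of their own
campaign. `runPipeline()` wires the whole chain together — simulate,
calibrate via the scene's own panels, smooth, denoise, index, train the
full roster under both strategies, apply the 5-unit rule, map the
first-campaign scene with the best selected retraining model, and score
plant-level recovery against the generator's truth.

## Numerical choices and problem sizes

* RNG: every stochastic step takes an explicit seed; helpers restore the
  caller's RNG state.
* GP optimisation: L-BFGS-B on log-parameters, bounds keeping length
  scales in e^-4..e^8 (standardized units); 100 iterations for
  prediction fits, 40 for ARD importance fits (relevance rankings
  stabilise early); a shared Cholesky cache serves the objective and its
  gradient; jitter 1e-8 on the kernel diagonal.
* Degenerate inputs fail loudly: constant responses (undefined R²),
  rank-deficient calibration bands, isotropic kernels asked for ARD
  scales, masks with unassigned plant ids, truncated cube files.
* Default test-scale problem sizes, chosen to keep the full suite
  comfortable on a single CPU: the five-campaign table at its study
  sizes (108/108/108/108/75), the 12 x 5 mini scene for end-to-end runs,
  50 seeds at n = 500, p = 20 for the consensus experiment, and 20
  paired seeds for the strategy experiment.

## Known limitations

* The synthetic leaf model has a single absorber degree of freedom;
  carotenoid/anthocyanin dynamics that several registry indices target
  are not independently simulated, so those indices are validated
  algebraically, not biologically.
* Field-scale accuracies reported for real campaigns are not
  reproducible from synthetic data and are not targets of this package's
  tests.
* The ENVI reader supports float32 BSQ/BIL/BIP with lowercase-key
  headers — the dialect the writer emits — not the full header zoo.
* PLSR weights, not regression coefficients, feed the importance
  analysis; with heavy multicollinearity (adjacent bands) ranks within a
  correlated block are arbitrary, which is precisely why the quartile
  consensus across three mechanisms, and band-range merging, are used.
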