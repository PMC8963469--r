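# chlorospec

Multi-temporal retrieval of SPAD-based leaf chlorophyll from hyperspectral
reflectance.

## What this package is for

Leaf chlorophyll tracked with a SPAD meter (a unitless transmittance index,
0–70) is the workhorse ground truth of crop phenotyping, but a handheld
meter cannot cover a field through a season. This package implements a
machine-learning workflow that extends leaf-level SPAD sampling to
wall-to-wall maps using 400–1,000 nm hyperspectral imagery (272 bands,
6 nm FWHM) collected over repeated field campaigns. It is written for
plant-phenotyping and remote-sensing researchers who want the full chain —
spectral preprocessing, vegetation-index construction, multi-model
regression with explicit temporal learning strategies, feature-importance
consensus, and pixel/plant-level mapping — as tested, seedable R functions
rather than a one-off script stack.

The core of the workflow:

* **Response and predictors.** SPAD readings *y* per leaflet are paired
  with predictor vectors *x*: all 272 reflectance bands, the 145 bands
  used by the index registry, or 60 pigment vegetation indices (nine
  groups, from NDVI-type greenness through derivative and
  continuum-removal indices).
* **Learning strategies.** *Sequential*: one model fit on all campaigns
  pooled. *Retraining*: models refitted as campaigns arrive on windows
  that track the crop's current state (t1; t1+t2; t2+t3; t3+t4; t4+t5),
  architecture and hyperparameters frozen after the first campaign;
  campaign *i* is predicted by model *i*.
* **Model roster.** 17 configurations across linear, PLSR, decision-tree,
  tree-ensemble (60 trees, boosted and bagged), support-vector
  (6 kernels) and Gaussian-process (4 kernels) families, scored by
  5-fold cross-validated R² = 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)² and validated by
  RMSE and MAE in SPAD units; models with validation RMSE or MAE above
  5 SPAD units (the meter's realistic error budget) are excluded.
* **Importance consensus.** Per-predictor relevance from PLSR component
  weights, random-forest impurity importance and ARD Gaussian-process
  length scales ("weakness index"), thresholded at the upper (PLSR, RF)
  or lower (GPR) quartile and combined into 1/2/3-method consensus
  counts.
* **Mapping.** Selected models applied per pixel under a plant mask;
  retrievals outside 0–70 become counted gap pixels; GPR maps carry a
  σ95 layer (1.96 × predictive SD); plant-level means follow the field's
  rows × columns sowing arrangement.

Because the original field data are not deposited, a first-class synthetic
module reproduces the study's structure — five campaigns of 108 (last 75)
leaflet samples with season-long SPAD dynamics, Beer–Lambert leaf spectra
with chlorophyll absorption features and a SPAD-driven red edge, and
ENVI-style mini data-cubes with soil background, gray calibration panels
and exact plant masks — so every stage is tested against known ground
truth.

## Worked example

```r
library(chlorospec)

out <- runPipeline(seed = 1)   # simulate -> calibrate -> train -> select -> map

# 17 models x 2 strategies scored on the held-out validation set
head(out$records[order(out$records$rmse), c("model", "strategy", "rmse", "mae", "r2")], 4)
#>                                               model   strategy   rmse    mae     r2
#> ensemble_bagged_rf_ret           ensemble_bagged_rf retraining 0.9909 0.7781 0.9904
#> ensemble_boosted_ret               ensemble_boosted retraining 1.0390 0.8475 0.9894
#> tree_medium_ret                         tree_medium retraining 1.3262 1.0274 0.9828
#> gpr_squared_exponential_ret gpr_squared_exponential retraining 1.3488 0.9911 0.9822

nrow(out$selection$selected)   # configurations passing the 5-unit rule
#> 28

out$bestModel                  # model used to map the first-campaign scene
#> "ensemble_bagged_rf"

out$recovery                   # plant cells recovered within 5 SPAD units
#> 1
```

`out$map` is a `PredictionMap` (per-pixel SPAD, gap-pixel count,
provenance); `out$plantAverages` is the 12 × 5 plant matrix next to the
generator's truth in `out$plantTruth`. Lower-level entry points —
`simulateSampleTable()`, `gaussianResample()`, `empiricalLineFit()`,
`mnfDenoise()`, `viRegistry()`/`computeAllIndices()`, `fitSequential()`/
`fitRetraining()`, `importanceAnalysis()`, `predictCube()`,
`plantAverage()` — expose each stage; the methods vignette
(`vignettes/spad-retrieval-methods.Rmd`) documents the models,
assumptions and parameter choices.

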