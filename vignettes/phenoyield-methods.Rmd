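---
title: "Plant-level yield prediction from multi-date UAV rasters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant-level yield prediction from multi-date UAV rasters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-resolution drone surveys of a crop trial produce, per flight date, a
digital surface model (DSM) and multispectral reflectance maps. From these,
per-plant secondary traits — canopy height and vegetation indices — can be
derived through the season and used to (a) find which traits at which growth
stages carry information about final yield and (b) predict plant-level yield
components: fresh shoot mass (SM, kg/plant), fruit weight (FW, kg/plant) and
fruit number (FN, count/plant). `phenoyield` implements that full chain for a
processing-tomato style field trial, together with a seeded synthetic-field
generator so every stage is testable without access to field data.

The pipeline is: simulate (or load) multi-date rasters → derive terrain,
plant-height and vegetation-index maps → segment plants and fix circular
regions of interest (ROIs) → extract 756 per-plant variables → select the
top-5 variables per trait with five algorithms → predict each trait with
three regression models, scored by held-out R² and relative RMSE.

## Maps

Plant height is `PH = DSM − DTM`. The digital terrain model is not observed:
it is estimated by keeping the DSM at bare-soil pixels (NDVI < 0.1) and
filling the elevation under vegetation by harmonic (Laplace) infill — each
canopy pixel is constrained to the mean of its four neighbours with soil
pixels as Dirichlet boundary, and the sparse system is solved exactly. We
chose harmonic infill over scattered-data interpolation because it is
deterministic, has no tuning parameters, and reproduces planar terrain
exactly (planes are harmonic functions); on the synthetic fields its RMS
error under canopy is well below the DSM sensor-noise level. Negative PH
values (surface below terrain, always interpolation/sensor noise) are
clipped to 0.

Three vegetation indices are computed per date:

* `NDVI  = (NIR − Red) / (NIR + Red)`
* `GNDVI = (NIR − Green) / (NIR + Green)`
* `WDVI  = NIR − a · Red`

where `a` is the slope of the soil line, the linear NIR-vs-Red relation of
bare soil. `a` is fitted per date by least squares over the NDVI < 0.1
pixels (a global constant can be supplied instead; whether one soil line per
date or per season is preferable is genuinely open — per-date tracks
illumination drift and is the default). Zero-denominator pixels become
missing rather than 0 so they can never contaminate ROI statistics.

## Plants and ROIs

Plant canopies are segmented at NDVI > 0.5, 8-connected components are
labelled, and components smaller than a 0.05 m-radius disc are discarded —
a deterministic stand-in for manual weed removal. Segmentation runs on the
earliest analysis date, when canopies are smallest and most separable. Each
component's centroid (mean world coordinates of its pixel centres) anchors a
circular ROI of radius 0.20 m; a pixel belongs to the ROI when its centre
lies within the radius, which is unambiguous and grid-resolution
independent. When canopies have merged into fewer components than the known
transplant grid, vegetated pixels are assigned to the nearest nominal
position and centroids recomputed — the transplant grid is known a priori in
a designed trial, so this resolves merges without manual digitisation. The
raster-centroid approximation can offset centroids slightly relative to
hand-digitised polygon centroids; on the synthetic preset the offset is
under 0.05 m, a quarter of the ROI radius.

## The 756 variables

Per plant, per date, per map (PH, NDVI, GNDVI, WDVI):

* five first-order statistics of the ROI values — mean (AVE), sample SD,
  adjusted Fisher–Pearson skewness, range, maximum;
* thirteen gray-level co-occurrence matrix (GLCM) texture measures — sum
  average, entropy, difference/sum entropy, variance, difference/sum
  variance, angular second moment, inverse difference moment, contrast,
  correlation, and the two information measures of correlation.

Plus, per map, the dynamic growth rate of the ROI mean between consecutive
dates (change divided by the day interval; 10 dates give 9 rates). The
accounting is `4 maps × 18 statistics × 10 dates + 4 × 9 = 756` columns,
named `<MAP>_<STAT>_<MMDD>` and `<MAP>_GR_<D1>-<D2>`; a first-order-only
candidate mode gives `4 × 5 × 10 = 200` columns. Growth rates are computed
per plant (per-plot rates could not reach the 756-column accounting).

GLCM choices the texture literature leaves open, fixed here as:

* gray levels N = 32, per-ROI min–max linear quantization with
  left-open/right-closed bins (min → 0, max → N−1; constant ROIs → level 0);
  the rule is invariant to affine rescaling of the map values;
* displacement offsets of one pixel in the four directions 0°, 45°, 90°,
  135°, symmetric accumulation; each direction is scored separately and the
  13 features are averaged over directions (the classic rotation-robust
  convention);
* natural logarithms in all entropies with `0·log 0 = 0`;
* sum variance computed as the positive dispersion
  `Σ (k − SA)² P_{x+y}(k)` about the sum average: a leading minus sign
  sometimes printed in front of this formula would make a non-negative
  dispersion negative, and centring on the sum average (rather than on sum
  entropy, another historical variant) keeps SV the exact second moment of
  the gray-level-sum distribution;
* degenerate conventions — correlation 0 when a marginal is constant, MOC1
  = 0 when `max(HX, HY) = 0`, the MOC2 argument clamped at 0 before the
  square root; a constant ROI yields ASM = IDM = 1 and all entropies,
  contrast and difference variance 0.

Masked (out-of-circle or missing) pixels are excluded from both
quantization and pair counting; only pairs with both pixels valid enter the
matrix. Every computed matrix satisfies `ΣΣ P = 1`, symmetry, and unit
marginal sums, and the whole feature set is verified against an
independently coded literal-formula oracle to 1e−10 in the tests.

Before selection, every column is centred and scaled to unit sample SD;
zero-variance columns are set to 0 and flagged.

## The synthetic trial

The generator emulates a three-replicate open-field trial: 5 × 5 m plots,
five rows per plot, 14 hills per row at 0.40 m spacing — 210 plants, the
layout a breeding trial of this size would use. (A row of 14 hills at
0.40 m is 5.2 m long; the generator derives its raster extent from the
spacings plus a 0.5 m margin, treating the nominal plot edge as
informational.) Ten acquisition dates span May 24 – July 24 (2020 calendar).

Dynamics, chosen to match the phenology of an open-field processing tomato:

* per-plant height follows a logistic curve with asymptote ~N(0.70, 0.07²) m,
  midpoint DOY 150 and rate 0.10/day, so height rises steeply until
  flowering (~DOY 160) and then plateaus;
* vegetated NDVI/GNDVI trajectories are Gaussian-in-time bumps peaking at
  DOY 184 (baselines 0.60/0.48, amplitudes ~N(0.35, 0.03²), width 26 days);
  the vegetated NIR trajectory peaks at DOY 194 so WDVI peaks ten days after
  the normalized indices; all decline afterwards as leaves senesce;
* canopies are isotropic Gaussian bumps (sd 0.12 m, truncated at 3 sd) whose
  footprint grows with the height curve; the height bump is additionally cut
  off at the optical canopy edge so that pixels classed as soil by NDVI
  never carry canopy elevation — without this, sub-threshold canopy fringes
  would leak decimetre-scale errors into the terrain model, which no real
  soil surface exhibits;
* bare soil sits on the soil line `NIR = 1.1 · Red` with spatially smooth
  red albedo (sd 0.025) plus white reflectance noise (sd 0.004); soil NDVI
  stays near 0.05, safely below the 0.1 threshold;
* within-canopy texture is a seeded Gaussian random field (correlation
  length 3 px) applied to the NDVI/GNDVI targets and the NIR level with a
  per-plant amplitude in [0.04, 0.12] that grows with canopy development,
  so GLCM features carry plant-specific signal; the DSM adds white noise of
  sd 0.005 m.

Yields are generated with known causal structure: five designated feature
columns (by default `NDVI_AVE_0618`, `PH_AVE_0626`, `WDVI_RANGE_0618`,
`NDVI_SV_0712`, `GNDVI_RANGE_0716` — early/mid fruit-formation variables of
all four maps, three first-order and two texture statistics) are evaluated
on the generated rasters *through the package's own feature engine*, and
each trait is a linear rule over them plus Gaussian noise. Relative weights
(0.5, 0.45, 0.4, 0.35, 0.3) act on standardized features and are rescaled so
the linear predictor has a coefficient of variation of 0.2 about the trait
means (SM 1.6 kg, FW 2.4 kg, FN 28 fruit); the noise SD is derived from a
target truth-R² of 0.8 (or given explicitly; 0 gives exactly linear
yields). FN is rounded and floored at zero. The realized raw-scale
coefficients, intercepts and noise SDs are returned so recovery tests can
regress generated yields on the causal features and match them to numerical
precision in the zero-noise case.

What the generator does *not* emulate: photogrammetric artefacts (bundle
adjustment error, mosaic seams), radiometric miscalibration, weeds, shadows,
occlusion between neighbouring plants, and non-linear trait physiology.
Passing tests therefore demonstrate that the pipeline recovers a known
ground truth through realistic geometry, phenology and noise — not that the
printed accuracies of any particular field campaign are reproduced.

The default ground sampling distance is 0.02 m/pixel (a survey-grade drone
flies 3–5 mm; 2 cm keeps a full 10-date run around a minute while leaving
~315 pixels per ROI, ample for 32-level texture statistics). All
randomness flows from a single integer seed; identical seeds give
bit-identical rasters and yields.

## Variable selection

Five algorithms rank the candidates per trait; each returns per-variable
importances, and stochastic methods are rerun with 10 derived seeds and
their importances averaged before the top five are taken (ties broken
lexicographically by column name, so results are reproducible and invariant
to column order). Desk-scale defaults, all configurable:

* **Boruta** (all-relevant selection): each iteration appends a permuted
  shadow copy of every candidate, fits a random forest (60 trees,
  permutation importance), and counts a hit when a real variable beats the
  best shadow; two-sided binomial tests at α = 0.01 with Bonferroni
  correction confirm or reject variables, rejected ones leaving the active
  set; up to 20 iterations. The importance score is the mean importance
  across iterations, so ranking works even for variables still tentative
  when the run budget ends.
* **Permutation importance** (model-agnostic): a random forest base learner
  (64 trees); importance is the increase in whole-sample RMSE after
  permuting a column, averaged over 2 permutations.
* **Genetic algorithm** (wrapper selection): binary chromosomes over the
  candidates; fitness is the negative 5-fold CV RMSE of a ridge fit on the
  selected subset minus 0.002 per variable; tournament selection (size 2),
  uniform crossover at 0.8, elitism 1, population 40, 40 generations,
  sparse initialisation (5% bits on) and per-bit mutation 1/p. A fixed
  mutation rate like 0.01 flips ~7–8 bits per child at p = 756 — almost all
  of them turning noise bits on — and empirically prevents convergence, so
  the mutation rate scales with the chromosome length. Importance is the
  selection frequency in the final generation.
* **LASSO**: an L1 path with the penalty chosen by 10-fold CV (`glmnet`);
  importance is the absolute coefficient at the chosen penalty, and exact
  zeros are rejected. On orthonormal designs the solution matches the
  soft-thresholding closed form, which the tests verify.
* **RFE** (recursive feature elimination): repeatedly fit a random forest
  (100 trees, impurity importance) and drop the weakest 10% of the
  remaining variables; the forest's out-of-bag RMSE per subset size acts as
  the cross-validation estimate that picks the optimal size (OOB is the
  forest's built-in resampling; explicit k-fold at every step would
  multiply cost several-fold for no accuracy gain at n ≈ 210). The top set
  is the optimal subset ranked by reverse elimination order, and may hold
  fewer than five variables when the optimal subset is smaller.

The base learners, repeat count and all hyperparameters above are the
package's own choices — the selection stage of this kind of study rarely
documents them — and are surfaced as function arguments.

## Prediction and evaluation

Plants are split 80/20 by a seeded uniform draw (210 plants → 168 train /
42 test). Hyperparameters are tuned inside the training split only: random
forest (500 trees) tunes variables-per-split by out-of-bag error on a
doubling/halving ladder around p/3; ridge tunes its L2 penalty by 10-fold
CV over a log-spaced grid reaching 1e−6 (so a noiseless linear rule is
recovered with R² ≥ 0.999); the radial-basis support-vector machine tunes
cost, kernel width and the ε-tube by 10-fold CV grid search. Reported
metrics come from the single held-out 20%: `R² = 1 − SS_res/SS_tot`
(the squared Pearson correlation is reported alongside, since the two
diverge for biased predictions), and `rRMSE = 100 · RMSE / mean(observed)`
— the usual crop-yield convention for the denominator. Within one trait all
models share the same split, so they are compared on identical held-out
plants. FN is treated as a continuous target and predictions are reported
unrounded. Because a single 42-plant test set leaves sampling noise in the
metrics, `repeated_split_eval()` optionally repeats the whole
split/tune/fit/evaluate cycle over independent partitions (20 by default)
and reports the dispersion of R² and rRMSE alongside the headline
single-split numbers.

One textual ambiguity had to be resolved: "held-out evaluation by tenfold
cross validation" is contradictory as stated; the only reading consistent
with an 80/20 split is tenfold CV *for tuning inside the training split*
and a single held-out test set for the reported metrics, which is what the
package does.

## Numerical and degenerate-input conventions

* Missing pixels propagate through every derived map; VI zero-denominators
  become missing, never 0.
* A plant ROI whose quantized patch has no valid co-occurring pair receives
  the constant-patch texture conventions and is logged, rather than
  aborting a 756-column assembly.
* Skewness of a constant sample is 0; sample SD and skewness use n−1
  (type-2) forms.
* All stage seeds are derived from one master seed by integer mixing below
  2³¹, so end-to-end runs are reproducible without per-stage bookkeeping.
* Rasters are exchanged as ESRI ASCII grids written with 17 significant
  digits, making write/read round-trips exact; this plain-text format plus
  an affine pixel-centre convention (row-major, north-up) is the package's
  native interchange format.

## Problem sizes used in the shipped analyses

The analysis scripts and the acceptance checks run the full 210-plant,
ten-date preset at 0.02 m resolution: scene generation ~10 s, map
derivation ~7 s, 756-column feature assembly ~15 s, the five selection
methods with 10 repeats a few minutes, and the prediction grid under two
minutes on one core. Unit tests exercise the same code paths on a 6-plant
plot. These sizes are the package's chosen desk-scale study conditions; all
of them are parameters.

## Known limitations

* The harmonic DTM assumes smooth terrain under canopies; sharp micro-relief
  (ridges, furrows) under a closed canopy cannot be recovered by any
  soil-pixel interpolation.
* Centroids come from raster components, not digitised polygons; with
  heavily merged late-season canopies the nominal-grid assignment resolves
  identity but inherits the transplant grid's accuracy.
* Selection recall is assessed against the generator's linear ground truth;
  correlated neighbours of a causal variable (e.g. SD vs RANGE of the same
  map-date) are frequently selected in its place, exactly as in real
  feature panels — the recovery criteria are therefore set against chance
  expectation, not exact identity.
* With n ≈ 210 and p = 756 the stochastic selectors' single-run rankings are
  noisy; the 10-repeat averaging is load-bearing and cheap relative to the
  feature engine.
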