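---
title: "Ensemble niche modelling with small-sample jackknife validation"
author: "nichecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble niche modelling with small-sample jackknife validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## Scope and model

`nichecast` estimates the area of environmental suitability (AES) of a
species known from very few spatially unique occurrence records, and its
change under future climate scenarios. The pipeline combines five
components: correlation-matrix PCA reduction of environmental blocks,
disk-constrained pseudo-absence sampling, a multi-algorithm ensemble,
leave-one-out (jackknife) validation with an exact Poisson-binomial
significance test, and majority-consensus mapping with spherical area
accounting. Everything downstream of the raster inputs is deterministic
given the run seed.

This vignette explains each component's assumptions, the tunable
parameters and their defaults, the design choices made where the design
was genuinely open, and what the synthetic validation studies do and do
not demonstrate.

## Environmental reduction

Environmental predictors arrive as two blocks — a climate block and an
edaphic/topographic block — of co-registered single-band rasters on a
regular lon/lat grid (cells are half-open, `[west, east) x (south,
north]`; row 1 is the northernmost row). The valid-cell mask is the
intersection of the per-layer masks: a cell missing in any variable is
excluded everywhere downstream.

Because the blocks mix units (°C, mm, soil fractions, metres), each PCA
is computed on the correlation matrix: variables are standardized to zero
mean and unit variance over valid cells before the rotation. The fitted
transform stores the standardization constants and the full orthonormal
loading matrix, and is *projected* — never re-fitted — onto future
stacks, so axis *k* means the same linear combination of anomalies in
every scenario. Edaphic axes are computed once from the current stack and
reused for all scenarios, since soil and terrain do not change on the
projection horizon.

Axis counts (`pca$climate$n_axes`, `pca$edaphic$n_axes`; defaults 6
and 2) may be fixed integers or `"broken_stick"`. The broken-stick rule
compares the observed variance proportion of axis *k* of *p* with the
null expectation `b_k = (1/p) * sum(1/i, i = k..p)` and retains the
maximal *leading run* of axes that strictly exceed it, with a floor of
one axis. The strict inequality and leading-run convention are tie-break
choices: spectra exactly on the null expectation retain one axis, and a
later axis that exceeds its stick after an earlier failure is not
rescued.

## Pseudo-absences

Most calibration algorithms need absences; with presence-only data,
pseudo-absence (PA) cells stand in. Eligibility follows a *disk* rule:
a cell qualifies if its haversine distance (sphere radius 6371 km, cell
centre to cell centre) to the **nearest** presence lies within
`[d_min, d_max]`. By default the band is the minimum and maximum over all
presence-pair distances; both are overridable (`pa$d_min_km`,
`pa$d_max_km`), which matters when the presences are few and nearly
equidistant — three near-equidistant points can leave a sliver band with
no eligible cells, which the pipeline reports as an error naming the
band.

PA counts per learner family follow the classification-tree
recommendation: GBM, CTA and RF receive as many PAs as presences; GLM,
GAM, ANN, FDA, MARS and MAXENT receive 10 000, capped with a warning at
the eligible-cell count on small grids. For the capped families the
presence class is weighted so both classes carry equal total weight.
`pa$n_sets` (default 10) independent PA sets are drawn per replicate, and
every learner is refitted on each.

## The learner registry

The ensemble is agnostic to its members: a registry maps family names to
fit/predict functions, and `register_learner()` accepts new ones. The
nine reference families are backed by standard estimators — xgboost
(GBM), rpart (CTA), randomForest (RF), stats::glm (GLM), mgcv (GAM),
nnet (ANN), MASS::lda on spline features (FDA), an L1-penalized
natural-spline logistic regression (MARS), and an L1-regularized logistic
regression on linear + quadratic + pairwise-product features of the PCA
scores (MAXENT — a deliberate, documented approximation of
maximum-entropy modelling; full Maxent is out of scope).

Default hyperparameters are chosen for the extreme-small-sample regime
this package targets, where an unpenalized flexible fit on a handful of
presences separates the classes perfectly and memorizes the training
cells — which silently destroys the jackknife (every replicate threshold
collapses onto saturated training scores that the withheld cell cannot
reach). The defaults therefore regularize every family:

| family | backend | key defaults |
|---|---|---|
| GLM | `stats::glm` + `stats::step` | BIC-penalized stepwise term selection |
| GAM | `mgcv::gam` | `k = 4` bases, `select = TRUE`, `gamma = 1.4` |
| CTA | `rpart` | `minsplit = 2`, `minbucket = 1`, `cp = 0.001` |
| RF | `randomForest` | `ntree = 100` |
| GBM | `xgboost` | `nrounds = 30`, `max_depth = 2`, `eta = 0.1` |
| ANN | `nnet` | `size = 3`, `decay = 0.1`, `maxit = 200` |
| FDA | `MASS::lda` | natural-spline features, `df = 2` |
| MARS | `glmnet` | natural-spline basis `df = 2`, lasso `lambda = 0.01` |
| MAXENT | `glmnet` | quadratic feature map, lasso `lambda = 0.01` |

All are overridable per family through the `hyper` configuration entry.
The regularization level trades two failure modes documented by the
package's recovery experiments: too little and models memorize (inflated
thresholds, failed jackknife replicates); too much and the fitted
response flattens, so projected climate shifts move too few cells across
the threshold and area losses are under-reported. Members with
non-monotone response shapes (quadratic or spline terms, trees) can also
project spurious "re-entry" into the niche on the far side of an optimum
under strong monotone shifts — a known extrapolation hazard of
correlative models that the recovery study quantifies.

Stochastic learners are reseeded from a deterministic derivation of the
run seed per (family, PA set, run); with `n_runs` repeated runs per PA
set, runs differ only by that seed, so deterministic families contribute
identical duplicates — matching an ensemble design of families × PA sets
× runs models per replicate (9 × 10 × 10 = 900 at reference settings).
Individual fit failures (e.g. a degenerate discriminant basis) are
skipped with a warning and excluded from the unweighted ensemble mean.

## Jackknife validation and the exact test

With *n* unique presence cells (cells of the analysis grid, ~10 km at
5 arc-min, holding at least one record), each cell is withheld in turn;
the distance band, PA draws and ensemble calibration use only the
remaining *n − 1* cells, and the withheld cell is barred from PA
eligibility — no information leaks into its replicate. The replicate's
continuous ensemble is thresholded by MaxSensSpec: sensitivity(t) is the
fraction of training-presence scores ≥ t, specificity(t) the fraction of
PA-cell scores < t (one score per distinct PA cell, pooled over both PA
designs), and the search runs over midpoints of adjacent distinct pooled
scores plus the extremes, breaking ties toward the smallest maximizing
threshold. All scenarios are binarized at the replicate's own threshold.

Success means the withheld cell is predicted present. A model no better
than random succeeds on replicate *i* with probability equal to the
area-weighted proportion *p\_i* of the landscape predicted present
(spherical-band cell areas, so polar cells count less), so the success
count is Poisson-binomial and `poisson_binomial_pvalue()` computes the
exact tail P(X ≥ D) by convolution — no normal approximation at n = 7.
A homogeneous-binomial variant (success probability = mean *p\_i*) is
available via `test = "binomial"`. The test is one-sided (better than
random); the trivial all-present model gets p = 1 because every
*p\_i* = 1. Note the test conditions on the realized predicted-area
proportions; it is exact given those, not an unconditional spatial test.

## Consensus and change accounting

Only replicates that predicted their withheld presence contribute to the
consensus; the frequency surface (mean of contributing binary maps) is
always emitted, and the consensus cell is 1 where the frequency reaches
0.5 — majority, ties to presence. If no replicate qualifies the
pipeline returns the validation report with a warning and no maps, since
a consensus of failed replicates would be meaningless.

Suitable area sums `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`
over present cells (R = 6371 km); the all-ones global 5 arc-min grid
reproduces the sphere's surface to within 0.01%. Scenario change is
reported as % loss (or gain) of total suitable area against the current
scenario, plus cell-wise stable/lost/gained areas — totals can mask
turnover, so both are reported. Polygon overlap counts a present cell
toward a polygon when its centre lies inside (even-odd rule, holes
honoured); partial-cell intersection is deliberately out of scope.

## The virtual-species simulator

`generate_env()` builds `latent_dim` (default 4) standardized latent
climate factors as smooth random fields — mild broad gradients, a
low-frequency wave, and a dominant smoothed-noise component. The
smoothed-noise weighting makes the landscape *patchy* (correlation length
of a few cells): fragmented habitat is the realistic shape for the
forest-mosaic systems this regime targets, and a range composed of many
patches gives area statistics many independent boundary segments instead
of a single frontier. Observed variables are random linear mixes of the
latents plus independent cell noise (`noise_sd`, default 0.3), each with
its own offset and scale so the blocks arrive in heterogeneous units; the
edaphic block mixes two separate latents. Defaults emulate the shape of
a 19-bioclim + 10-edaphic stack on a 100 × 100 grid of 5 arc-min cells
in south-western Amazonia.

A virtual species is `plogis(intercept + sum(weights * latents))` — a
logistic function of the *latent* factors, not the observed variables, so
the PCA step has a genuine signal subspace to recover. Presences are
drawn without replacement with probability proportional to true
suitability. Future scenarios displace the latent factors;
`latent_shift()` converts a latent displacement into per-variable
additive shifts (in sd units) of the observed climate layers, keeping the
edaphic block bit-identical, and `shift_for_loss()` root-finds the
displacement along the species' weight direction that removes a requested
fraction of true suitable area.

The validation studies fix two species: a **strong** species with
weights (6, 3, 0, 0) and intercept −4 — an odds ratio of e⁶ per standard
deviation of the leading factor and a prevalence near 0.27, the
sharp-range, locally common regime for which presence-only modelling is
best posed — and a **null** species with zero weights (suitability 0.5
everywhere, presences uniform). Study sizes are 60 × 60 grids with 20
presence cells for recovery experiments, 30 × 30 with 7 (null) or 20
(signal) cells for the calibration studies, and reduced ensembles (three
families × 3 PA sets × 2 runs, or a single fast family for the 250-run
calibration batteries). The 7-cell setting mirrors the motivating
field situation; 20 cells is the power regime where success/failure
statistics are informative run by run. The calibration batteries fix the
disk bounds at 30–400 km rather than using the presence-pair defaults:
seven *uniformly scattered* null presences frequently produce degenerate
presence-pair bands (no cell is far enough from its nearest presence),
which is an artifact of the null design, not of the method under study.

## What the validation studies show — and don't

* **Exact-test oracles.** The Poisson-binomial tail matches full 2ⁿ
  enumeration for n ≤ 12 and the closed-form binomial tail for equal
  probabilities; the MaxSensSpec threshold attains the optimum of an
  exhaustive 10⁻⁴-grid scan; broken-stick selection matches direct
  harmonic summation. These are correctness proofs of the statistics.
* **Geometry.** Cell areas integrate to the globe (0.01%) and to the
  85.86 km² equatorial 5 arc-min cell.
* **Identities.** Projecting the current transform onto the training
  stack reproduces the fitted scores to 10⁻¹⁰; a future scenario
  identical to the present yields bit-identical consensus maps and
  exactly 0% change under fixed seeds.
* **Disk sampling.** Sampled PA sets match a brute-force eligibility
  enumeration on grids up to 50 × 50.
* **Recovery.** For true losses of 20/50/80% the reported loss is within
  ±15 percentage points in at least 8 of 10 seeded runs per level.
* **Calibration.** On null species the jackknife rejects at 5% in ≤ 10%
  of 200 runs; on strong species with 20 cells it rejects in ≥ 90% of 50
  runs.

These demonstrate internal correctness and recoverability under the
generator's assumptions: smooth latent fields, a monotone logistic
species on those fields, presences sampled from suitability without
observation bias, and co-registered error-free rasters. They do *not*
demonstrate robustness to spatially biased sampling, label noise,
niche–climate disequilibrium, dispersal limits, or truncated calibration
ranges — all real-data hazards outside this package's scope. Reported
loss percentages remain threshold-relative: they quantify change of the
modelled suitable area, not of occupied range.

## Numerical and degenerate-input choices

* Thresholds use strict candidate enumeration (no grid), ties to the
  smallest maximizing value; `suitability >= threshold` maps to presence,
  so threshold 0 marks every valid cell present.
* The Poisson-binomial convolution is exact in O(n²) and underflows only
  beyond n ≈ 10³ replicates, far above any realistic jackknife.
* Zero-variance layers abort the PCA by name; single-class training
  tables, unknown families, empty eligible-cell sets, zero qualifying
  consensus maps, and out-of-grid occurrence sets all fail fast with
  specific messages.
* All stage seeds derive from one run seed via a fixed integer recurrence
  (32-bit safe), so any stage can be replayed in isolation.

## Known limitations

The MAXENT family is a regularized quadratic logistic approximation, not
Maxent's full feature/regularization schedule. Consensus is plain
majority; no evaluation-weighted ensemble is offered because the design
averages unweighted. Polygon overlap is centre-in-polygon. Rasters are
exchanged as ESRI ASCII grids and polygons as GeoJSON; reprojection,
resampling and terrain derivation belong to GIS preprocessing, not to
this package.
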