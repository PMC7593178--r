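---
title: "Models and methods in habtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in habtune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habtune)
options(habtune.quiet = TRUE)
```

habtune trains, tunes and evaluates species distribution models (SDMs)
in a single framework: a samples-with-data (SWD) container, four model
families behind one train/predict contract, three evaluation metrics,
data-driven variable selection, and three hyperparameter tuners
including a genetic algorithm. This vignette explains the models, the
design decisions behind them, and what the package's synthetic
benchmarks can and cannot demonstrate.

## The SWD data model

Presence-only SDMs contrast the environmental conditions at species
observations against a set of *contrast* locations: random *background*
points (presence-background designs, required by the Maxent-style
method) or confirmed *absences* (presence-absence designs, used by the
classification methods). An `SWD` object stores one row per record —
species label, X/Y coordinates, binary presence flag and covariate
values — and every other function consumes and returns it. Coordinates
are carried as metadata only; no model ever sees them.

Two validation strategies are supported. `splitHoldout()` partitions
presences and contrasts independently (so both partitions keep the
class balance), with per-class test sizes `round(n * fraction)` and
halves rounded down — a documented rule so counts are exactly
predictable. `randomFolds()` builds class-stratified k folds whose
within-class sizes differ by at most one; stratification guarantees
every fold holds both classes, which an unstratified split cannot.
Externally built folds (e.g. spatial blocks) enter through
`importFolds()`, which validates the same invariant. All partitioning
is a pure function of (data, parameters, seed).

## Model families and their hyperparameters

| method | backend | tunable hyperparameters (defaults) |
|---|---|---|
| ANN | nnet | hidden-layer size (number of variables), weight decay (0), initial weight range (0.7), iterations (100) |
| BRT | xgboost | trees (100), interaction depth (1), shrinkage (0.1), bag fraction (0.5) |
| RF  | randomForest | trees (500), variables per split (`floor(sqrt(p))`), minimum node size (1) |
| ME  | native | feature classes (`lqph`), regularization multiplier (1), iterations (500) |

The boosted-regression-tree surface keeps the classical BRT
hyperparameter names; xgboost provides the gradient-boosting engine
(single thread, seeded, deterministic). The ANN hidden-layer size has
no universal default and resolves to the number of variables when
unset.

### The native Maxent-style method

The ME method is implemented natively — no Java runtime is involved in
training or prediction. Covariates are expanded into Maxent's feature
classes: linear (x), quadratic (x²), product (all pairwise xᵃ·xᵇ) and
hinge. Hinge features use 20 knots per variable per direction
(configurable), placed at equally spaced empirical quantiles of the
combined presence + contrast values; a forward hinge is
max(0, x − t)/(max − t) and a reverse hinge max(0, t − x)/(t − min), so
every hinge column runs from 0 at one end of the training range to 1 at
the other. All columns are min-max scaled to [0, 1] on the training
ranges, and those ranges are stored: at prediction time covariates are
clamped to them before feature evaluation, so extrapolation beyond the
training range is flat by construction.

Coefficients solve an L1-penalized presence-vs-background binomial
likelihood (presence weight 1, background weight 100 — the standard
approximation of the infinitely weighted logistic regression). The
per-feature penalty is

λⱼ = m · sd ⱼ(presences) / √(n_presence)

for linear/quadratic/product features (sd floored at 0.05 so a feature
constant among presences is not free) and λⱼ = m · 0.5 / √(n_presence)
for hinge features (a constant per-class budget), where m is the
regularization multiplier. The exact per-class penalty tables of the
Java implementation are deliberately not reproduced; what the package
guarantees — and tests — is monotone complexity control: the spread of
predictions is non-increasing in m, and m → ∞ recovers the null model
(uniform raw output). The convex optimization itself is delegated to
glmnet along a descending 200-step lambda path ending at
mean(λ) · n_presence / Σweights, the same division of labor the field's
R implementation of Maxent uses. Non-convergence within the iteration
budget is recorded as a note on the model, never thrown, so tuning
loops that probe low iteration counts cannot abort.

Outputs: `raw` = exp(η)/Z with Z summing exp(η) over the training
background (raw sums to 1 there by construction); `cloglog` (the
default) = 1 − exp(−e^H · raw) where H is the entropy of the raw
distribution over the training background; `logistic` =
e^H·raw/(1 + e^H·raw). Tables with more than 10,000 background records
are downsampled (seeded) to that cap before fitting.

## Evaluation metrics

- **AUC** is the rank-based Mann–Whitney estimate: the mean over all
  presence-contrast pairs of 1/0.5/0 (higher/tied/lower). Background
  records count as negatives — standard presence-background practice;
  the resulting AUC is then bounded away from 1 by the species'
  prevalence, which matters when interpreting the synthetic benchmarks
  below.
- **TSS** = sensitivity + specificity − 1 under the rule
  "score ≥ t ⇒ presence", maximized exactly over the distinct observed
  scores (not a fixed grid). Threshold ties break toward the highest
  sensitivity, then the lowest threshold. Whether the boundary uses ≥
  or > is a convention; ≥ is adopted and documented.
- **AICc** = 2k − 2lnL + 2k(k+1)/(n−k−1), available for the ME method
  only: k counts non-zero feature coefficients (intercept excluded),
  n is the number of presences, and lnL sums the log of the raw score
  normalized to 1 over the evaluation extent — the full raster when
  supplied, otherwise the table's background (a documented desk-scale
  deviation knob). AICc uses all observations, accepts no partition,
  and is undefined (NA, flagged not thrown) when n − k − 1 ≤ 0.

With k-fold validation the reported validation value is the arithmetic
mean of the per-fold values.

## Variable importance and data-driven selection

`permutationImportance()` shuffles one covariate column at a time
(presences and contrasts jointly, 10 permutations by default), records
the mean drop of the training metric, clamps negatives at zero and
normalizes to a 100% scale (a uniform split when every drop is zero —
the degenerate all-uninformative case). `jackknifeDrop()` retrains the
model once per candidate variable with that variable removed, keeping
method, hyperparameters and seed fixed.

`varSel()` removes collinearity: rank variables by permutation
importance; find the most important variable correlated at
|ρ| ≥ threshold (Spearman by default, on the contrast records,
optionally subsampled) with any other; jackknife its correlated group
on the **training** metric; discard the member whose removal costs
least; retrain; repeat until no pair reaches the threshold. The focal
variable itself competes for removal (set `protectFocal = TRUE` for the
alternative reading); ties break toward lower permutation importance,
then name order, for reproducibility.

`reduceVar()` removes low-importance variables. Without the jackknife
it strips the lowest-importance variable while it falls below the
threshold, re-ranking after every removal. With the jackknife a
sub-threshold variable is removed only if the **validation** metric
after retraining does not drop; variables that fail the check are
marked necessary and the loop continues until every sub-threshold
variable is removed or proven necessary.

The train/validation asymmetry is deliberate: collinearity pruning
should preserve the information captured from the training data (tuning
controls overfitting later), while parsimony pruning exists to improve
generalization and must therefore be licensed by validation
performance. Both functions remove exactly one variable per step —
removing a variable changes the importance ranking of the survivors —
and never produce a model with zero predictors.

## Hyperparameter tuning

`gridSearch()` evaluates every combination of a `hyperGrid`;
`randomSearch()` evaluates a uniform without-replacement sample of
them (20 by default). `optimizeModel()` runs a genetic algorithm:

1. initialize the population with `randomSearch` (size 20);
2. rank by fitness — the validation metric, with an *underfitting
   guard*: combinations whose validation score exceeds their training
   score rank last (for AICc-driven tuning the ranking is simply
   ascending AICc and the guard is disabled, since no partition
   exists);
3. retain round(size × 0.4) of the best plus round(size × 0.2) drawn
   uniformly without replacement from the remainder (round-half-to-even,
   so the retained counts are reproducible);
4. refill the population with children: two distinct parents drawn
   uniformly from the retained set; each hyperparameter inherited
   uniformly from one parent; with probability 0.4 one hyperparameter
   is mutated to a uniform draw from its domain excluding both parents'
   values (skipped when no third value exists);
5. repeat for 5 generations.

Training requests therefore total
size + generations × (size − keptBest − keptRandom) — 60 under the
defaults — and the package asserts this count on every run. A child
duplicating an already-evaluated combination is served from a cache
keyed by combination identity (the count above counts *requests*; cache
hits are logged separately), so nothing is ever fitted twice. With zero
generations the algorithm *is* random search, and the two functions
return identical evaluation sets under the same seed. Elitism makes the
best retained fitness non-decreasing across generations.

Interactive real-time charts are out of scope here; every selection and
tuning step instead emits a structured log line (suppress with
`options(habtune.quiet = TRUE)`), and `modelReport()` renders static
figures.

## The virtual-species simulator

`simulateSpecies()` provides ground truth for every test in the
package. Base layers are smooth Gaussian random fields — white noise
circularly convolved (FFT) with an isotropic Gaussian kernel of width
`smoothness` cells — standardized to mean 0, sd 1. Controlled
distortions can be injected: `duplicates` replaces a layer with another
plus Gaussian noise (a collinear pair with known Spearman ρ), and
`noiseLayers` generates a layer as *unsmoothed* white noise. The
distinction matters: a smooth layer with coefficient 0 is not pure
noise within a single landscape realization, because its spatial
chance-alignment with the suitability surface is shared between
training and validation cells drawn from the same landscape; only the
white-noise layer is uninformative in the strict sense.

True suitability is logistic,
s = 1/(1 + exp(−(β₀ + Σⱼ βⱼ xⱼ))). Presences are drawn without
replacement with probability proportional to s (so sample sizes are
exact, rather than Bernoulli-per-cell), absences proportional to 1 − s,
background uniformly without replacement.

Default study conditions, fixed once: an 80 × 80 landscape, smoothness
5 cells, three layers with coefficients (3, −2, 0), intercept −4, and
500 presences, 500 absences, 2000 background points. The intercept
deserves a word: it sets the species' prevalence (≈ 0.15 of the
landscape). Presence-background AUC is bounded by prevalence — a
species occupying half the landscape cannot exceed ≈ 0.73 AUC even with
a perfect model — so a localized species, as presence-only studies
typically target, is the meaningful default; with it, the true
suitability scores ≈ 0.87 AUC and a correctly specified model matches
that.

What the simulator does *not* emulate: sampling bias, spatial
clustering of occurrences, observation error, interactions or
non-monotone responses, and non-stationary covariate correlation.
Passing benchmarks on it therefore demonstrate algorithmic correctness
(the right variable is removed, the optimizer finds the grid optimum,
budgets and invariants hold) — not field performance on real occurrence
data.

## Numerical conventions

- Round-half-down for hold-out test sizes; round-half-to-even for GA
  retention counts; both documented so counts are testable.
- Hold-out and fold assignment, sampling, permutation and the GA all
  draw from an isolated RNG stream seeded per call; the caller's RNG
  state is restored afterwards.
- TSS/threshold candidates are observed scores only; `binarize()` uses
  ≥, and missing cells stay missing through raster prediction and
  thresholding.
- Derived feature columns are clipped to [0, 1] at prediction time:
  after clamping a covariate to its training range, a derived column
  (e.g. x² when the range spans 0) can still fall below its training
  minimum.
- SWD files are written with 17 significant digits and a dot decimal
  regardless of locale, so write → read is an exact round trip.

## Problem sizes used in the shipped benchmarks

The test-suite and acceptance benchmarks run on synthetic species at
desk scale, chosen as the smallest sizes at which the studied effects
are stable: 50 × 50 landscapes with 150 presences / 400 background
points for unit-level checks, and the full default conditions (80 × 80,
500/2000, 80/20 split) for the selection postconditions and the
end-to-end workflow. The tuning benchmarks use grids of 32–1200
combinations; the GA-vs-grid comparison uses a 48-combination grid so
the exhaustive optimum is computable.

## Known limitations

- The ME penalty calibration is a faithful *shape* (per-feature,
  sd-scaled, multiplier-proportional) but not the Java implementation's
  exact table; absolute AICc values are comparable within this package
  only.
- Percent-contribution importance (a Java-internal quantity) is not
  implemented; permutation importance is used everywhere.
- Spatial-block fold construction and spatial thinning are out of
  scope; external folds can be imported.
- Raster I/O uses single-band TIFFs with a JSON sidecar (layer min/max
  and geotransform); no CRS handling or projection.
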