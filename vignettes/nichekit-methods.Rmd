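---
title: "Models and methods behind nichekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nichekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichekit)
```

nichekit implements the full inference chain used in ensemble
species-distribution modelling (SDM) of invasive species: occurrence
preparation, an eight-family model ensemble selected by AUC and the true
skill statistic (TSS), scenario projection with spherical-area and
centroid-shift accounting, and niche-dynamics quantification between a
native and an invaded range. This vignette explains the models, the
numerical choices, and what the synthetic validation data can and cannot
show.

## The modelling problem

Presence-only occurrence records are contrasted with pseudo-absence
(background) points drawn uniformly from the non-presence cells of the
environmental grid. Each of eight model families learns a map from predictor
values to a suitability score in $[0, 1]$:

* **GLM** — binomial regression with linear and quadratic terms per
  predictor.
* **CTA** — a single classification tree (rpart, default pruning).
* **RF** — a 500-tree random forest.
* **GBM** — stagewise boosted trees (depth 3, learning rate 0.01, up to
  2500 rounds) with early stopping on an internal stratified 20% holdout.
* **ANN** — a one-hidden-layer network (5 units); weight decay is chosen
  from $\{10^{-3}, 10^{-2}, 10^{-1}\}$ by internal 3-fold cross-validated
  AUC.
* **FDA** — linear discriminant analysis on a fixed hinge + quadratic basis
  expansion (knots at the predictor quartiles), a desk-scale analogue of
  flexible discriminant analysis on an adaptive-spline basis.
* **MaxEnt** — the penalized presence–background logistic regression that is
  equivalent to maximum-entropy density ratio estimation (the
  infinitely-weighted logistic form), on linear + quadratic + hinge
  features, with a lasso penalty tuned by seeded cross-validation. The
  background weight is 10: large enough that presences behave as a point
  process against background intensity, small enough that the coordinate
  descent path is numerically stable at these sample sizes.
* **SRE** — the surface range envelope: a per-variable percentile envelope
  (2.5–97.5% by default) fitted on presences only; prediction is 0/1
  envelope membership.

These recipes are fixed and documented rather than inherited from any other
toolkit's "defaults"; the contract is the shared fit/predict interface,
score bounds, and the performance invariants the test suite checks.

### Replicate design and evaluation

`run_replicates()` draws stratified random 75/25 train/test splits
(presences and pseudo-absences split together), repeats 10 times by
default, and fits every family on every split: 8 families × 10 repetitions
= 80 single models. Each model is scored on its holdout by

* **AUC**, computed by the Mann–Whitney midrank formula (ties count ½), and
* **max-TSS**: $TSS(t) = \text{sensitivity}(t) + \text{specificity}(t) - 1$
  maximized over all observed score thresholds, with "suitable" meaning
  score $\ge t$. Threshold ties break toward the smaller cutoff — the more
  inclusive suitable area, which is the conservative choice for invasion
  early warning.

### Ensemble construction

Families are ranked by the mean of their mean AUC and mean TSS; the top
three form the ensemble. All successful replicate models of those families
become committee members, and the ensemble score is their unweighted mean,
scaled to the integer $p \in [0, 1000]$ once at output (a TSS-weighted mean
is available). The binarization cutoff $c$ is recomputed per run: every
replicate's holdout is scored by that replicate's members, the pooled
holdout predictions give one max-TSS threshold, and that single $c$ is
reused for every scenario projection. The four-class map partitions
$[0,1000]$ at $c$, 400 and 600 (unsuitable / low / moderate / high); the
scheme requires $c < 400$ and `classify4()` rejects anything else.

### Variable importance and response curves

Permutation importance of a variable is $1 - r$, where $r$ is the Pearson
correlation between ensemble predictions on the data and on the data with
that column permuted, averaged over seeded permutations and clamped to
$[0, 1]$. Response curves use the evaluation-strip convention: one variable
sweeps a grid while all others sit at their background mean; the suitable
range of a variable is the union of maximal intervals where the curve
reaches 0.6 — the highly-suitable level on the 0–1 scale.

## Geography

Grids are geographic (WGS84, degrees), cell-center registered, row 1 at the
northern edge. Cell areas use the exact spherical band formula
$R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bot})$ with
$R = 6371$ km, so class areas, gain/loss bookkeeping and area-weighted
centroids are exact on the sphere; centroid shifts use the haversine
distance and spherical initial bearing. Suitable-area centroids are
area-weighted means of suitable cell centers (unweighted and $p$-weighted
variants exist); longitudes are averaged arithmetically, so a suitable
region straddling the antimeridian is an error rather than a silent wrap.
Future scenarios are parametric perturbations of the baseline stack —
additive or multiplicative shifts per layer; non-climatic layers are simply
left untouched, which mirrors holding human-influence and topography
constant across futures.

## Niche dynamics in environmental space

The niche space is the plane of the first two principal components of a PCA
fitted on the pooled (centered, scaled) background environments of both
ranges; occurrences are projected onto the same axes. A 100 × 100 grid
spans the pooled background scores with a 5% margin.

Occupancy on that grid is the availability-corrected density
$z \propto o / e$: $o$ is the Gaussian kernel density of the occurrences,
$e$ of the background, each with per-axis Silverman rule-of-thumb
bandwidths. Two numerical choices matter:

* **Background support.** $z$ is set to 0 wherever $e$ falls below the 5th
  percentile of the background density evaluated *at the background points
  themselves*. A quantile over raw grid values would be meaningless — a
  Gaussian KDE is positive everywhere and spans dozens of orders of
  magnitude, and cells with $e \approx 10^{-22}$ would otherwise swallow
  the normalized occupancy through their $o/e$ ratios.
* **Bandwidth.** The Silverman rule is
  $0.9\,\min(\hat\sigma, IQR/1.34)\,n^{-1/5}$ per axis (`bw.nrd0`), passed
  through `MASS::kde2d`'s $h/4$ convention.

Overlap and dynamics:

* **Schoener's D** $= 1 - \frac12\sum|z_1 - z_2| \in [0, 1]$, symmetric.
* **COUE indices**: within the analog environment (cells with background
  support in both ranges, densities renormalized there), expansion $E$ is
  the invasive occupancy where the native occupancy is zero, stability
  $S = 1 - E$ exactly, and unfilling $U$ is the native occupancy where the
  invasive occupancy is zero.
* **Equivalency test**: pooled occurrences are re-split at random into the
  original sample sizes (100 reps by default) and D recomputed against the
  fixed backgrounds. The primary p-value is lower-tailed with the +1
  permutation correction, so p is never 0 and equivalency is rejected when
  the observed overlap is *lower* than the permutation null; the upper tail
  is also reported.
* **Similarity test** (each direction): the test range's occupancy density
  is relocated rigidly to a random cell of its own background support; D
  against the fixed other range forms the null, upper-tailed. Small p means
  the niches match beyond what background availability alone explains.
* **PNO profiles**: suitability-weighted histograms of one environmental
  variable, normalized to sum 1, for overlay comparison between ranges.

## The virtual-species generator

All validation runs on synthetic data with known ground truth, emulating
the shape of a real invasion analysis (global occurrence table, bioclim-like
raster stack, a native and an invaded region):

* **Landscapes** are seeded white noise smoothed by a separable Gaussian
  kernel (sd 5 cells by default) and standardized per layer — spatially
  autocorrelated fields with N(0, 1) marginals on an 80 × 80 grid of
  0.1° cells. Kernel smoothing was chosen over variogram simulation for
  speed and simplicity; tests only need controllable autocorrelation.
* **The species** responds to two driving variables through Gaussian
  response curves (optimum 0, breadth 0.35 in predictor units) and is flat
  on a nuisance layer; per-variable responses multiply. Breadth 0.35 makes
  a realistic specialist (~6% of the landscape at suitability ≥ 0.5) whose
  Bayes-optimal presence/background AUC, $(b^2+1)/(2b^2+1) \approx 0.92$,
  leaves the model families room to perform well without being trivial.
* **Occurrences** (500 per range by default) are drawn with probability
  proportional to suitability and placed at cell centers, so grid thinning
  is exactly testable; a jitter flag adds within-cell noise.
* **The invaded region** reuses the native region's climate field,
  translated geographically, so the two ranges offer identical
  environmental availability. This is the controlled setting a
  virtual-species experiment needs: at niche offset 0 the two occurrence
  sets are exchangeable and the equivalency permutation test is calibrated.
  With independent field realizations (available via
  `shared_landscape = FALSE`) the test also reacts to availability
  differences between the ranges — as it does between real continents —
  and its p-values at offset 0 concentrate low.
* **Niche shifts** displace the invasive species' driving optimum by a
  chosen offset; offsets of 0–4 breadths span full conservatism to strong
  divergence. **Futures** are additive shifts on the temperature-role
  driver, increasing across the three built-in scenario tags.

What passing tests on these data do **not** show: robustness to sampling
bias, coordinate error, non-Gaussian or interacting responses, dispersal
limitation, or availability asymmetry between ranges — real-data features
the generator deliberately omits.

## Problem sizes and determinism

The default study conditions (80 × 80 landscapes, 500 occurrences per
range, 1000 pseudo-absences, 10 repetitions, 100-cell niche grid, 100
permutations) run end-to-end in well under a minute on one CPU; the test
suite's recovery and calibration experiments use 20–50 seeded replicates of
the same conditions. Every stochastic step takes its own sub-seed, derived
from the master seed by hashing the stage name and replicate index
(`derive_seed()`), so a run is a pure function of its configuration and
seed across machines.

## Known limitations

* The thinning rule keeps the first record per cell; there is no
  occurrence-weighting or environmental filtering.
* PCA-env restricts niche dynamics to two components; structure orthogonal
  to that plane is invisible, and with isotropic synthetic backgrounds the
  plane's orientation is rotation-arbitrary.
* The similarity-test null relocates the whole density rigidly; it cannot
  represent nulls where only part of the niche shifts.
* Classes are only well-formed when the data-derived cutoff stays below
  400 on the 0–1000 scale, as in the implemented classification scheme;
  strongly balanced designs can push the max-TSS cutoff above it, in which
  case `classify4()` refuses rather than reshuffling the boundaries.

```{r example, eval = FALSE}
# A complete run at the default study conditions:
run <- run_pipeline(default_config(), seed = 1)
glance(run$ensemble)   # members, pooled AUC/TSS, cutoff
glance(run$niche)      # D, expansion/stability/unfilling, test p-values
autoplot(run$maps[["native"]])
```
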