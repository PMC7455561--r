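---
title: "Ensemble distribution modelling and niche overlap: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble distribution modelling and niche overlap: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleosdm)
```

# The modelling problem

Presence-only distribution modelling asks: given the locations where a
species was recorded and rasters of environmental predictors, which parts
of the landscape are environmentally suitable? Because systematic absence
data rarely exist — least of all for extinct taxa known only from
archaeological or fossil sites — the standard design contrasts presence
records against *background* cells drawn from the landscape, fits several
complementary algorithms, and combines them into an ensemble. Comparing
two species' normalized suitability surfaces with Schoener's *D* then
quantifies how much their reconstructed niches coincide — for instance a
predator against each of its candidate prey.

`paleosdm` implements that entire chain, with a virtual-species module so
every stage can be validated against *known* truth: a species with a
planted response curve is sampled from a synthetic landscape, the
pipeline reconstructs it, and the reconstruction is checked against the
parameters that generated the data.

# Pipeline stages and their parameters

## Occurrence filtering

Raw records pass three stages, with counts logged at each (`raw` →
`deduplicated` → `thinned`):

* **De-duplication** keeps one record per raster cell (or per cell of an
  explicit lattice), removing exact and cell-level duplicates.
* **Spatial thinning** enforces a minimum pairwise distance, 5 km by
  default — the conventional filter against spatial sampling
  autocorrelation. No standard algorithm is mandated by practice, so the
  package uses randomized greedy removal: while any conflict remains,
  delete a point with the most neighbours closer than the threshold,
  breaking ties by seeded RNG; the run is repeated (default 100 times)
  and the largest surviving set kept. On all enumerable fixtures (≤ 15
  points) this matches the exhaustive maximum-retention optimum, which
  the test suite verifies by brute force.
* Distances are great-circle (haversine, sphere radius 6 371.0088 km)
  for geographic coordinates and Euclidean for projected ones.

## Terrain predictors and collinearity

Slope is computed by Horn's 8-neighbour weighted differences, the default
of the standard terrain toolchains; border cells, nodata cells, and cells
adjacent to nodata are masked rather than estimated from fewer
neighbours. Topographic heterogeneity is the sample standard deviation
(denominator n − 1) of fine-scale elevation within each coarse block,
e.g. 90 m cells aggregated in 11 × 11 blocks to a ~1 km grid; it is
invariant to elevation shifts and scales linearly with relief.

Collinear predictors are filtered by stepwise VIF: VIF_j = 1/(1 − R²_j)
from the OLS regression of predictor *j* on the others, iteratively
dropping the largest until all fall below the threshold. The default
threshold of 10 is the convention of the usual stepwise implementations;
exactly collinear groups lose their later-listed member first, so the
procedure is deterministic.

## The five algorithms

All five fit presence (1) against background (0) and predict suitability
in [0, 1]:

| algorithm | form | defaults |
|---|---|---|
| `glm` | logistic regression, linear + quadratic term per predictor | predictors standardized; ridge fallback on non-convergence |
| `gam` | logistic additive model, penalized cubic splines | ~4 effective df per predictor (`k = 5`), REML |
| `gbm` | stochastic gradient-boosted trees, Bernoulli objective | 2 000 trees, learning rate 0.01, depth 3, bag fraction 0.5 |
| `maxent` | L1-regularized exponential model over feature expansions | linear + quadratic; hinge and product added at ≥ 80 presences; regularization multiplier 1 |
| `rf` | random-forest class probability | 500 trees, class-balanced bootstrap |

The quadratic GLM terms are what allow a unimodal (niche-shaped) response;
without them a logistic model can only fit monotone curves. The maxent
model is fitted by infinitely-weighted logistic regression (background
weight 100) with a lasso path whose final penalty scales like the
presence count over the total weight, mirroring the standard maxnet
construction; the fitted exponential density is normalized over the
background sample (the test suite checks the normalization to 1e-6), and
mapped to [0, 1] by the complementary log-log transform
1 − exp(−e^H · raw), where H is the entropy of the fitted density — the
standard Maxent output. Projection clamps predictors to their training
range, as Maxent conventionally does.

Stochastic members (gbm, rf, and any tie-breaking) take explicit seeds;
prediction after fitting is deterministic for all five. The bagging
algorithms resample training rows by position, so their results depend on
the declared seed (and on row order), while glm/gam/maxent are
order-invariant — the contract the tests enforce.

## Evaluation

With no true absences, background points stand in for absences in the
binary metrics, and this is stated in all reports:

* **AUC** in the Mann–Whitney form (fraction of presence/background score
  pairs ranked correctly, ties ½) — invariant to monotone transforms.
* **Sensitivity, specificity, TSS** at the threshold maximizing
  sensitivity + specificity, scanned over all observed scores (ties take
  the lowest threshold). TSS = sensitivity + specificity − 1 holds by
  construction.
* **Continuous Boyce index**: 101 moving windows of width 10 % of the
  score range; per window, the predicted-to-expected ratio
  F = P(presence scores inside) / E(landscape scores inside); the index
  is the Spearman correlation of F with the window midpoint. Windows
  with E = 0 are dropped; a degenerate range, fewer than three usable
  windows, or a constant F profile returns 0 with a warning.

Model calibration runs on a single random 80/20 split of presences (and
of background), with `round(n × fraction)` records in training — a
45-record set yields 36/9. The split seed is a required input, and every
run logs it.

**A note on the Boyce sample.** The hold-out fifth of a ~200-record
presence set leaves ~40 points, and a 101-window P/E profile built from
40 points is dominated by sampling noise (across seeds we observed
spreads of ±0.2 and worse under the null). The package therefore
evaluates AUC/TSS strictly on held-out data but computes the Boyce index
over the *full* presence set against the landscape profile — the
presence-only calibration convention, which is stable at these sample
sizes. Both score vectors are available to callers who prefer otherwise.

## Ensembles, importance, area

The ensemble map is the cellwise weighted mean of the member maps —
uniform weights by default, or each member's TSS (clipped at zero,
renormalized). Permutation importance of a predictor is
1 − cor(predictions, predictions after permuting that column), averaged
over 10 seeded repeats and clipped to [0, 1]; a predictor the model
ignores scores ~0. Binary maps threshold the ensemble at its max-TSS
threshold (recorded in the output metadata), and suitable area sums
per-cell areas — cellsize² for projected grids, cosine-corrected by row
latitude for geographic ones.

## Niche overlap

Schoener's *D* = 1 − ½ Σ|p_i − q_i| and Hellinger-based
*I* = 1 − ½ Σ(√p_i − √q_i)² are computed between surfaces normalized to
sum to one over their *common* valid support: cells that are nodata in
either map are dropped from both before renormalization, so the two
distributions always live on the same cells. Both metrics are symmetric,
bounded in [0, 1], equal 1 exactly on identical surfaces and 0 on
disjoint supports. Overlap is computed on continuous ensemble surfaces,
not binary maps — binary overlap would discard the suitability gradient
that gives *D* its 0–1 semantics.

# The synthetic study conditions

## What the generator emulates

`generate_env_stack()` produces one spatially autocorrelated field per
predictor: white noise smoothed with a separable Gaussian kernel
(circular convolution, default σ = 5 cells) — cheap, stationary, and
sufficient for testing, though not a substitute for realistic terrain.
Cross-correlations between predictors are imposed *exactly* on the
sample by empirically decorrelating the fields and mixing them with a
square root of the target correlation matrix; the final rescaling onto
each predictor's target range is affine, so the imposed correlations
survive. Non-PSD correlation matrices are rejected with the offending
eigenvalue. The default grid is 200 × 200 cells of 1 km in a projected
CRS, so distances and areas in tests are exact integers.

Virtual species have known per-predictor responses (Gaussian or
logistic) combined by product or geometric mean; with Gaussian responses
and product combination, suitability is exactly 1 at the joint optimum
and exp(−½) one σ away on a single axis — the closed forms the unit
tests assert. Presences are sampled with probability proportional to
suitability (the "probabilistic" virtual-species design) and jittered
within their cell; thresholded sampling would destroy the suitability
gradient that response-curve recovery and the Boyce index need.

## Why the study conditions look the way they do

The packaged landscape (`study_scenario()`) spans Bio5 10–50 °C, Bio6
−25–10 °C, Bio12 50–2 000 mm, TH 0–300 m — a semi-arid plateau flanked
by wet mountains. One design point deserves emphasis: a min-max rescaled
Gaussian field has a *bell-shaped* value distribution, so a niche
optimum placed mid-range sits at the landscape mode and is nearly
indistinguishable from background (with Bio12 on 100–1 200 mm, the true
suitability of a 600 mm specialist separates presences from background
at AUC ≈ 0.61 — an upper bound no fitted model can beat). Placing the
600 mm optimum in the wetter tail of a 50–2 000 mm landscape, with a
specialist's niche width of σ = 75 mm, makes the planted species
genuinely separable (true-suitability AUC ≈ 0.91) — this was verified
with the *generating* response functions, not with fitted models, and
then frozen. The packaged species (`study_species()`) are: `montane`
(Bio12-only specialist, for response-curve and importance recovery),
`predator` and `goatlike` (very similar two-axis niches), and
`gazellelike` (an arid-hot niche whose precipitation optimum lies 3.5–4.7
σ from the montane one, plus a +10 °C shift in Bio5).

## What passing tests do and do not show

The generator's fields are smooth, stationary, and Gaussian; real
climate layers have terrain-locked structure, skewed distributions, and
sampling bias in the occurrence record, none of which are emulated.
Passing the recovery tests shows the *pipeline* is correct — that given
data whose generating process matches the model assumptions, the chain
of thinning, fitting, ensembling and overlap recovers the truth. It does
not certify performance on any real landscape.

# Numerical choices and conventions

* Cells are half-open: a cell owns its left and top edges; row 1 is the
  top row. Point extraction takes the containing cell's value, with no
  interpolation.
* Thinning, splitting, sampling, permutation importance and all
  stochastic fits take explicit integer seeds; the pipeline derives
  per-stage seeds from one global seed by stage-name hashing, so stages
  can be rerun in isolation.
* Threshold ties resolve to the lowest candidate threshold; conflict-count
  ties in thinning resolve by seeded RNG.
* GLM non-convergence falls back to a small-ridge fit (λ = 10⁻³) and the
  fallback is recorded on the model object.
* Degenerate inputs fail loudly: all-zero suitability, empty score
  vectors, constant predictor columns, non-PSD correlation matrices and
  disjoint raster extents are rejected with explanatory errors rather
  than silently coerced.
* Rasters are exchanged as ESRI ASCII grids — a plain-text,
  GDAL-readable format; the CRS kind (projected metres vs geographic
  degrees) is supplied by the caller since the format does not carry it.

# Known limitations

* **Plain-mean ensembles inherit member scale.** The five algorithms
  return differently calibrated scores: the prevalence-calibrated members
  (glm/gam/gbm) produce small values on a 2 %-prevalence background
  design, while the maxent cloglog output has a larger mean and a
  nonzero floor over unsuitable cells. A cellwise mean therefore lets
  the maxent layer dominate the *normalized* ensemble surface, which
  inflates Schoener's *D* between well-separated single-axis niches: at
  exactly 3 σ separation on one predictor, ensemble-based *D* stays
  near 0.5–0.6 even though the glm/gam/gbm members individually yield
  0.14–0.19. Niches separated across the full niche space (the packaged
  `predator` vs `gazellelike` pair) are resolved cleanly (*D* ≈ 0.3 vs
  ≈ 0.95 for identical niches). Overlap users who need sharper contrast
  should compare single-algorithm surfaces or rescale members before
  combining.
* The Boyce index has high sampling variance at small presence counts
  regardless of implementation; see the evaluation note above.
* Spatial cross-validation, coordinate-uncertainty handling, and
  occurrence sampling bias are out of scope; the single random split
  mirrors the simplest standard design.

# Problem sizes used by the test suite

The validation runs use the packaged study conditions at full size — a
200 × 200 km landscape, 200 presences, 10 000 background cells, all five
algorithms — for the recovery and overlap checks, and reduced grids
(50–120 cells a side) for unit-level checks where the full landscape adds
nothing. The complete suite, including four full ensemble fits and two
end-to-end demo pipeline runs, finishes in roughly ten minutes on one
CPU.
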