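---
title: "Multi-scale seascape models of fish distributions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale seascape models of fish distributions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fish on tropical shelves distribute themselves along two broad axes: the
topographic structure of the seafloor (reefs versus flat sand) and the
geographic position across the shelf (nearshore to shelf edge). `reefscape`
models species occurrence from a single input — a high-resolution
bathymetric grid — by deriving terrain morphometrics and cross-shelf
distance predictors at several spatial scales, fitting two presence models
(stochastic gradient boosted regression trees and a maximum-entropy Gibbs
model), and evaluating both the statistical fit (cross-validated ROC AUC)
and the mapped product (threshold-based accuracy at independent sites).
Because real surveys and regional LiDAR cannot ship with a package, a
synthetic seascape generator with fully known response structure stands in
for them: every claim the test suite makes is checked against that ground
truth.

## Terrain morphometrics

Six morphometrics are computed from the depth grid with 3×3 neighbourhood
operators, all treating the raster values as a height field:

* **depth** — the input passed through;
* **slope** (degrees) — arctangent of the gradient magnitude from Horn's
  weighted finite differences, the de facto GIS standard;
* **aspect** (degrees clockwise from grid north) — downslope direction;
  nodata where the gradient vanishes;
* **slope of slope** (degrees) — the slope operator applied to the slope
  raster; a second-derivative measure of topographic complexity, the
  package's main "rugosity of position" variable;
* **plan curvature** (1/m) — the transverse (contour-tangential) second
  derivative from a quadratic surface fit; the sign convention is negative
  = convex (bumps, ridges), positive = concave (channels, bowls). Cells
  with zero gradient have no contour direction and are assigned 0;
* **rugosity** (ratio ≥ 1) — triangulated surface area over planar area in
  the 3×3 window (eight 3-D triangles through the half-way edge points).
  This construction is exact on planes: a uniform slope θ gives exactly
  1/cos θ.

Border policy: any cell whose full 3×3 support (5×5 for slope of slope)
touches the grid edge or a nodata cell is nodata. Horn's stencil does not
use the center cell, so the center's validity is enforced explicitly;
nothing ever leaks into masked regions.

## Multi-scale predictors

Each morphometric is averaged inside a circular moving window at each
radius of interest (defaults 5, 25, 50, 100, 300 m). Kernel membership is
by cell-center distance ≤ radius, which makes the 5 m window on 4 m cells
the 5-cell plus shape. Aspect, a direction, is averaged on the circle via
unit vectors (350° and 10° average to 0°, and opposing bearings yield
nodata, not 180°). A focal mean is reported only where at least
`min_valid_fraction` (default 0.5) of the kernel holds valid data, so
large-radius means are never dominated by a handful of edge cells.

Focal sums are computed by FFT convolution; valid-cell counts are integers
and are rounded after the transform, so the result agrees with direct
summation to ~1e-12 relative — the unit tests pin this against explicit
per-cell summation at 1e-9.

Two scale-independent layers complete each stack: Euclidean
distance-to-shoreline and distance-to-shelf-edge, computed from contour-band
masks with an exact two-pass distance transform (center-to-center distances,
verified against an exhaustive min-over-mask scan). Features are extracted
at survey points by nearest-cell lookup — survey transects are larger than
a 4 m cell, so sub-cell interpolation would add false precision.

## The synthetic seascape

The generator emulates a shallow insular shelf mapped by bathymetric LiDAR:
a cross-shelf depth ramp (default 1–49 m over the grid width at 4 m cells)
with

* alongshore **shoreline undulation** (default amplitude 300 m) and, out of
  phase, **shelf-rim undulation** (200 m), wavelength 500 m — embayments
  and a sinuous rim, so the two distance predictors are not mirror images;
* broad **bank/depression relief** (default sd 4 m, wavelength ~1.5 km,
  tapered nearshore) — mid-shelf banks and channels, so depth is not a mere
  proxy for cross-shelf position. On real shelves depth carries local
  structure unrelated to shelf position; without this term all cross-shelf
  predictors are affinely collinear (r > 0.99) and no method could
  attribute an effect to a *distance* rather than to depth;
* Gaussian **patch reefs** (default 40 patches, 3 m relief, ~50 m across)
  rising from the seabed;
* white vertical noise (default sd 0.1 m).

With patches, noise and banks all zeroed the column means increase strictly
seaward — the monotone construction the terrain oracles rely on.

Hardbottom/softbottom strata are defined by a cellwise rugosity cut: a cell
is hardbottom where the pre-noise surface is rougher than the patch-free
seabed at that cell, i.e. exactly where patch reefs add roughness. Survey
sites are stratified-random: drawn uniformly without replacement within
each stratum at cell centers.

Species are simulated from an explicit logit response — linear terms, step
thresholds (an abrupt ecological threshold at a stated predictor value) and
pairwise products — evaluated on the predictor stack at the survey sites.
When a target prevalence is requested the intercept is solved by monotone
root finding; on 10^5 sites the expected prevalence matches the target to
well under 0.1%. True probabilities are stored with the draws so that
downstream models can be scored against ground truth.

What the generator does *not* emulate: biological spatial autocorrelation
beyond the stated response, detection error, habitat-class mosaics, tides or
hydrodynamics. Passing tests therefore demonstrate that the machinery
recovers known structure of this statistical form at survey scale — not
that any particular real species behaves this way.

## Boosted regression trees

`brt()` fits a stagewise additive logistic model under Bernoulli deviance:
at each stage one regression tree of depth ≤ `tree_complexity` is fit to
the gradient residuals (y − p) of a random `bag_fraction` subsample
(default 0.50, without replacement), with leaf values given by a single
Newton step and shrunk by `learning_rate`. Splits are exhaustive over
midpoints of sorted unique values with a minimum leaf of 10 observations;
ties break to the first (column-order) candidate, so a fit is a
deterministic function of the data, the configuration and the seed.
`tree_complexity` is the interaction order: depth-1 stumps give a purely
additive model, depth-2 admits two-way interactions, and so on.

The number of trees is the loss-minimising count on a k-fold
cross-validated predictive deviance curve, evaluated every
`cv_eval_stride` trees with ties toward fewer trees; the per-fold held-out
AUC at that count is reported with its standard error. Folds are stratified
by class — at a few percent prevalence an unstratified fold can hold no
presences at all and leave both deviance and AUC undefined. For
survey-scale data the slow learning rates of common practice
(0.0001–0.001, thousands of trees) apply unchanged; the package's examples
and tests use faster desk-scale settings (learning rate 0.01–0.05, a few
hundred trees) so the whole suite runs in minutes.

Variable importance is the summed squared-error improvement of all splits
on each variable, rescaled so the top variable scores exactly 100. Partial
dependence is Friedman's: the mean logit-scale prediction over the training
rows with the target variable(s) pinned to grid values, centered to mean
zero; by default the average runs over an evenly spaced subsample of
training rows (200 for curves, 100–150 for surfaces), which changes
nothing detectable at these n but keeps 28-pair scans fast. Interaction
strength for a pair is the variance of the two-way partial-dependence
surface around its row+column (main-effects) decomposition, ×1000 for
readability: exactly zero for any stump model, and a pure ranking statistic
— its absolute scale has no external calibration.

## Maximum entropy

`maxent()` fits the Gibbs distribution q(x) ∝ exp(λ·f(x)) over background
cells that maximises the penalised mean log-likelihood of the presence
sample with the L1 penalty Σ βⱼ|λⱼ|, βⱼ = (regularisation multiplier) ×
sⱼ/√m. This is the probability distribution of maximum entropy subject to
the relaxed constraints |E_q[fⱼ] − presence mean of fⱼ| ≤ βⱼ — the KKT box
conditions, which the tests verify numerically (tolerance 1e-6 against β of
order 0.1). Features default to standardised linear + quadratic + product
expansions of the eight predictors (44 features); hinge features are
omitted — the synthetic responses are smooth or single-step, and the convex
problem stays small. The optimiser is a coordinate-wise proximal Newton
with damping and active-set sweeps; the contract is the optimum, not the
algorithm, and restarts from random initial weights agree in objective to
the convergence tolerance because the problem is concave. Background
sampling is uniform over valid cells without replacement (default 10,000),
and presence cells legitimately appear in the background — it is a
background sample, not a set of absences.

Predictions: `raw` is the normalised Gibbs probability (summing to 1 over
the training background, checked at 1e-8); `logistic` = plogis(H + log
raw), with H the fitted background entropy, so a cell of typical background
suitability scores 0.5; suitability maps are 100 × logistic on the 0–100
scale. Jackknife importance refits the model with only, and then without,
each raw predictor's features, reporting regularised training gains
relative to the uniform model.

## Evaluation

ROC AUC uses the Mann–Whitney midrank formulation (equals the trapezoidal
area under the empirical curve; complements sum to 1; invariant under
monotone transforms of scores). For presence-only models, pseudo-absence
AUC scores held-out presences against seeded draws from the background;
with an exhaustive draw it reduces exactly to the plain AUC. Discrimination
bands follow the Hosmer–Lemeshow interpretation (0.7–0.8 acceptable,
0.8–0.9 excellent, > 0.9 outstanding; boundaries to the lower band). Map
accuracy converts a 0–100 suitability map to binary at a strictly-greater
threshold (default 10) and scores the percentage of independent *presence*
sites on suitable cells; validation absences are deliberately not scored —
the statistic asks how many actual sightings the map would have predicted,
and the package documents this asymmetry rather than hiding it behind the
word "accuracy".

One caveat the package surfaces deliberately: stratified-random surveys are
not exchangeable with a uniform background. If sites oversample hardbottom,
the pseudo-absence AUC of even a predictor-free ("null") species sits
above 0.5 — a survey-design bias, not an algorithm defect. The null-model
tests therefore allocate sites in proportion to stratum area.

## The experiment pipeline

`run_experiment()` drives the full design from one configuration object
(or YAML file): simulate the seascape, build stacks at each radius,
simulate each species over a stratified training survey, fit BRT and
MaxEnt per species × scale, and score cross-validated AUC, importance,
partial dependence of the top four predictors, optional pairwise
interaction matrices, 0–100 suitability maps, and map accuracy against an
independently drawn validation survey (default n = 360, its own seed). All
artifacts are written with an md5 manifest and a deterministic log;
re-running an identical configuration reproduces identical checksums. The
report tables mirror the natural shapes for this design: AUC by species ×
scale with best-scale flags per algorithm, selected BRT settings
(`n_trees`, `learn_rate`, `tc`, `cv_deviance`, `se`), and map accuracy
with a mean row.

## Numerical choices and degenerate inputs

* All stochastic stages take explicit integer seeds; every generator,
  split, bag and draw is reproducible bit-for-bit.
* Tree split ties: first candidate in column order; tree-count ties: fewer
  trees; a CV minimum at the largest tree count warns that the bound was
  hit.
* Aspect means with resultant length < 1e-6 are nodata (no preferred
  direction); zero-gradient cells have plan curvature 0 and aspect nodata.
* Contours absent from a grid's depth range raise an error naming the
  offending level; empty masks, empty kernels, single-class responses,
  non-finite features and schema mismatches all fail fast with named
  messages.
* MaxEnt stops on the KKT subgradient violation (1e-8 target), not on
  objective stagnation, and warns above 1e-3; zero-variance features are
  dropped with a warning, and a model with no informative features is the
  exact uniform distribution.

## Identifiability and limitations

Cross-shelf predictors are intrinsically correlated: depth,
distance-to-shore and distance-to-shelf all track the same axis. The bank
relief and rim undulations bound that correlation away from 1, but on a
steep simple ramp the boosted trees may still express a distance threshold
through depth — the effect is recovered, the *label* is ambiguous. The
interaction-recovery test therefore runs on a low-gradient platform
seascape (depth range 18–38 m) where the attribution is identifiable;
users analysing real ramps should read importance of depth and the
distances jointly. Problem sizes throughout the tests — grids up to
200 × 1500 cells at 4 m, surveys of 1000–1500 sites, backgrounds of
2000–5000 cells, 100–600 trees at learning rates 0.02–0.05 — were chosen
as the smallest at which these structures are statistically identifiable,
and the suite states expectations at those sizes. The pseudo-absence AUC
inflation noted above is reported, not corrected; kappa/TSS statistics,
calibration curves and mixed-model comparisons of AUC across algorithms
are out of scope.
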