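---
title: "Modelling seabed microlitter storage potential: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seabed microlitter storage potential: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seabedmp models the abundance of microplastic particles in seafloor
sediment (particles per kg dry weight) as a function of physical seabed
properties, and turns the fitted model into a relative *storage potential*
map that can be overlaid with polygon layers of litter sources and
sensitive receptors. This vignette explains the model, the selection
procedure, the diagnostics and the overlay, and records the design
decisions behind every tunable default.

## The model

The response is the station-level microplastic count `MP` and the
candidates are ten seabed predictors `X1, ..., X10`:

    MP = f(X1, X2, ..., X10) + error

`f` is a stochastic gradient-boosted ensemble of regression trees under
squared-error loss. The model starts at the training-response mean; each
iteration draws a fresh subsample of rows, fits a small tree to the current
residuals, and adds `shrinkage` times that tree to the fit. The defaults
are the configuration used throughout the survey analysis this package
implements:

| parameter | default | meaning |
|---|---|---|
| `ntrees` | 400 | boosting iterations |
| `depth` | 1 | split levels per tree (1 = stump) |
| `minobs` | 10 | minimum observations per terminal node |
| `shrinkage` | 0.1 | learning rate |
| `bag_fraction` | 0.5 | per-tree row subsample (without replacement) |

`ntrees`, `depth` and `minobs` are the tuned values for a survey of ~56
complete stations; `shrinkage` and `bag_fraction` are the conventional
stochastic-boosting defaults, exposed in `boost_params()` because the
tuned triple does not pin them down. The response is used untransformed: a
`log_transform` switch exists on the selection functions (fit on
`log1p(MP)`, back-transform with `expm1`) but is off by default, because
replicated-LOOMAE experiments on data of this shape favour the raw scale.
Depth values other than 1 are supported by the same split search applied
recursively, but only stumps are exercised by the default configuration;
treat deeper trees as an extension.

### Split search and tie-breaking

Candidate splits are midpoints between consecutive distinct sorted values
of each feature, restricted to candidates leaving at least `minobs` rows on
both sides. The best split maximizes the SSE reduction; exact ties resolve
to the lowest feature index, then the lowest threshold, so fits are fully
deterministic. When no candidate reduces the SSE (constant targets,
infeasible `minobs`), the tree collapses to a single leaf holding the
residual mean — degenerate trees still count toward `ntrees`, so the
ensemble size is always honoured.

### Randomness and reproducibility

Every random draw in the package flows through `derive_seed()`, a Lehmer
mix of a master seed and integer offsets (stage, replicate, left-out case,
tree index). Per-tree bags are drawn without replacement by a partial
Fisher–Yates shuffle driven by a minimal-standard generator seeded with
`(seed, tree index)`, which makes each tree's subsample independent of the
order in which trees are grown and keeps the whole pipeline a pure
function of (data, parameters, master seed). Leave-one-out passes for
depth-1 models run in a specialized compiled path that reuses per-feature
presorted row orders; it reproduces the generic per-fit path to ~1e-12
(the agreement is asserted in the test suite).

## Model selection

With 56 complete observations a held-out validation split would leave too
few cases on either side, so performance is measured by leave-one-out
cross-validation under mean absolute error:

    LOOMAE = (1/N) * sum_j | MP_j - MPhat_j |

where `MPhat_j` is the prediction for case `j` from a model fitted to the
other `N - 1` cases. Absolute error is used so a handful of badly
predicted stations cannot dominate the criterion. Because boosting is
stochastic, a single LOOMAE value is noisy: `replicated_loomae()` repeats
the full LOO pass with distinct derived seeds and reports the mean and
spread (100 replicates at survey scale; tests and examples use 10 or
fewer).

The selection procedure is:

1. **Permutation importance** on the full ten-predictor model fixes the
   variable ordering. Per replicate, the model is refitted with a fresh
   seed, its training MAE recorded, and each predictor column permuted in
   turn; the importance contribution is the MAE increase. The literature
   contains several permutation-importance estimators (out-of-bag vs
   training evaluation, refit vs reuse); the training-set refit variant
   used here was chosen for determinism and desk-scale cost, and
   individual values can be slightly negative by sampling noise — only
   the ranking is interpreted.
2. **Forward selection in importance order**: for k = 1..10, compute the
   replicated LOOMAE of the model using the k most important predictors.
3. **Best subset** = the first k variables at the curve minimum, with
   exact ties resolved toward the smaller (more parsimonious) model.
   `tune_parameters()` applies the same criterion over a grid of boosting
   configurations, with ties resolved to the earliest grid entry.

## Residual diagnostics

Survey stations cluster spatially, so LOO error estimates would be
optimistic if residuals were spatially autocorrelated.
`empirical_semivariogram()` implements the Matheron estimator

    gamma(h) = (1 / (2 |N(h)|)) * sum_{(i,j) in N(h)} (z_i - z_j)^2

with pairs binned by great-circle (haversine) distance into equal-width
bins up to half the maximum pairwise distance — both standard variography
conventions; a planar option serves synthetic tests whose coordinates are
already in km. Empty bins are reported with a zero pair count and an
undefined semivariance rather than being silently dropped. Because "no
obvious autocorrelation" is ultimately a judgement call,
`semivariogram_envelope()` adds a 199-permutation Monte-Carlo envelope
(values shuffled over locations); the package reports the curve and the
envelope and makes no automatic pass/fail claim. No variogram model is
fitted and no kriging is performed.

## Projection and risk overlay

`predict_surface()` evaluates the selected model at every grid-cell
centre. The surface is a **relative, unitless storage-potential score**:
predictors on a national grid are not guaranteed to share the calibration
of the survey stations, so the package never relabels surface values as
measured concentrations. An optional affine rescale to a user-stated range
exists for presentation, off by default.

Polygon exposure uses cell-centre containment (a centre on the boundary
counts as inside), matching how a visual overlay reads, rather than
area-weighted intersection; polygons containing no cell centre are
reported as no-data, never silently zero. Mean polygon abundance is
classified into four bands: the published integer bands 0–1000 (low),
1001–2000 (moderately elevated), 2001–3000 (elevated) and above 3001
(highly elevated) particles/kg are applied to real-valued means with the
half-open convention `[0,1000] (1000,2000] (2000,3000] (3000,Inf)`, so
e.g. 1000.0 is low and 3000.5 is highly elevated. Per-band percentages
are computed over classified polygons only (full precision in machine
output, integers in the printed report). Whether such percentages should
be computed over polygons or over grid cells is a genuine choice; polygon
means were chosen because the exposure unit of interest (an MPA, a
disposal site) is the polygon.

## The synthetic-data generator

`generate_station_dataset()` emulates the statistical structure the
analysis assumes, so the whole pipeline is testable without external data:

- **Stations**: gaussian scatter (sd 0.3 degrees) around uniformly placed
  cluster centres in a shelf-sized box, reproducing the close station
  spacing that motivates the semivariogram check.
- **Predictors**: i.i.d. standard-normal scores. Five default names carry
  effects in the default generating model (salinity range, wave orbital
  velocity, percent silt, seafloor curvature, nitrogen content); the other
  five are documented placeholders. The names are configuration, not
  semantics.
- **Response**: baseline + sum of per-predictor component effects,
  truncated at zero, with negative-binomial noise (size 2) by default.
  Effect sizes are set so simulated counts span roughly 0–7000
  particles/kg with a coefficient of variation around 0.7, matching the
  scale and overdispersion of published shelf-sediment surveys. Gaussian
  and noiseless options exist for controlled tests.

The recovery experiments (tests and the acceptance script) use a gaussian
variant with five comparable strong effects and noise sd 200, giving a
signal-to-noise ratio (sd of the deterministic signal over noise sd) of
about 3.7 — comfortably above the factor-3 floor at which recovery of the
informative subset is a reasonable ask at n = 56.

What the generator does **not** emulate: real bathymetry or predictor
rasters, correlated predictors, covariate-dependent station placement, or
measurement error in the predictors. Passing tests therefore demonstrate
that the machinery is correct and that the procedure recovers structure
it is designed to find — not that any particular real-world selection is
right.

## Numerical choices and degenerate inputs

- Exact SSE ties in the split search are broken deterministically (lowest
  feature, lowest threshold); constant targets short-circuit to a leaf.
- `replicated_loomae()` reports `sd = NA` for a single replicate rather
  than 0.
- Spatial field simulation adds a 1e-8-scale jitter before giving up on a
  non-positive-definite covariance.
- Model JSON is written with 17 significant digits so reloaded models
  predict bit-identically; station/grid CSV uses `%.17g` for the same
  reason.
- Stage timings go to a human-readable `run_log.txt`; every
  machine-readable artifact (CSV/JSON/GeoJSON) is byte-identical across
  reruns with the same configuration and master seed.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration (n = 56, ten
predictors, 400 stumps, `minobs` 10) with 10 LOOMAE replicates per curve
point and 20 master seeds for the recovery experiments; estimator-level
checks run at n up to a few hundred points, and Monte-Carlo checks use
500 field realizations. These sizes were chosen so the whole suite
completes in a few minutes while keeping Monte-Carlo standard errors well
inside the asserted tolerances.

## Known limitations

- Only squared-error boosting is implemented: no alternative losses,
  random-forest mode, or monotonicity constraints.
- Permutation importance is one member of a family; rankings, not
  magnitudes, are the supported interpretation.
- No spatially blocked cross-validation: the semivariogram check is a
  diagnostic, not a correction.
- The storage-potential surface is relative; converting it to absolute
  concentrations requires calibration information the model does not
  carry.
- GeoJSON support covers Polygon features with `{name, kind}` properties;
  shapefiles and multipolygons are out of scope.
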