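---
title: "Modelling deep-time habitat suitability for warm-water coral reefs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deep-time habitat suitability for warm-water coral reefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoreef)
```

## The problem

Warm-water coral reefs are confined today to tropical and subtropical
latitudes, with a minimum sea surface temperature of roughly 18 °C widely
regarded as the dominant physiological limit. Over geological timescales the
reef belt has expanded and contracted, and disentangling the climatic signal
from the changing distribution of shallow marine substrate requires a
model-based approach: calibrate a habitat suitability model (HSM) on the
modern reef distribution, project it onto reconstructed stage-level climate
and bathymetry, and ask how well the hindcasts anticipate the fossil reef
record.

`paleoreef` implements that entire pipeline as reusable, tested components:
raster plumbing on regular latitude–longitude grids, a from-scratch
presence–background maximum entropy (Maxent-style) model, bootstrap
replication and hindcasting, evaluation metrics (AUC, continuous Boyce
index, LTP and MaxSSS binary thresholds, MESS novelty surfaces), fossil
validation against random-point null models with one-sided Wilcoxon tests,
and spatiotemporal summaries (area-weighted hemispheric centroids, the
"reef zone", habitat area in 20° latitudinal bins). Because the data sources
such an analysis consumes are typically proprietary (commercial
palaeo-digital-elevation models, licensed climate simulations, curated reef
databases), the package ships a seeded synthetic-world generator that
reproduces the *statistical structure* of those inputs, so every stage of
the pipeline runs, and is verifiable, on any machine.

## The maximum entropy model

Presences and background are grid cells of the shallow-water mask (marine
cells with substrate depth strictly between 0 and 200 m, approximating the
photic zone). Each cell carries four climatic predictors: mean-maximum and
mean-minimum sea surface temperature (°C) and mean-maximum and mean-minimum
insolation (W m⁻²). Features are the four linear terms plus their squares,
each rescaled to $[0,1]$ using the background minimum and maximum. The model
is the Gibbs distribution over background cells

$$q_\lambda(x) \;=\; \frac{e^{\lambda \cdot f(x)}}{Z(\lambda)},
\qquad Z(\lambda) = \sum_{x \in \text{background}} e^{\lambda \cdot f(x)},$$

with weights chosen to minimise the L1-regularised objective

$$J(\lambda) \;=\; -\frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i)
\;+\; \log Z(\lambda) \;+\; \sum_j \beta_j |\lambda_j|,
\qquad \beta_j = \beta\, s_j / \sqrt{m},$$

where $m$ is the number of presence cells, $s_j$ the presence-sample
standard deviation of feature $j$, and $\beta$ a single global multiplier
(default 1). This is deliberately simpler than the interpolated
feature-class tables of the reference Maxent implementation: a single
documented rule is reproducible and its behaviour is easy to reason about.
At $\beta = 0$ the optimum satisfies exact moment matching
($E_q[f_j]$ equals the presence mean of $f_j$), which the test suite
verifies to $10^{-5}$.

The objective is convex; it is minimised by cyclic coordinate descent with
per-coordinate Newton steps, soft-thresholding for the L1 term, and a
backtracking line search on the exact one-dimensional objective, so every
accepted step decreases $J$. Convergence is declared when a full sweep
changes the objective by less than `tol` (default $10^{-7}$), with a cap of
5000 sweeps. The contract is the objective value, not the algorithm: the
suite checks fitted objectives against Nelder–Mead restarts on the identical
function to $10^{-4}$.

Continuous output uses the entropy-based logistic transform
$p = e^{H} q / (1 + e^{H} q)$, where $H$ is the entropy of the fitted raw
distribution over the background (implicit prevalence 0.5). The transform is
strictly increasing, so AUC is identical on the raw and logistic scales. A
consequence worth knowing: the logistic 0.5 level is *not* calibrated to the
species' true occupancy probability — on the synthetic world the 0.5 contour
sits a few °C warm of the truth's 18 °C midpoint. Range-limit recovery is
therefore assessed geographically (see "What the tests show") rather than
through the 0.5 contour.

Hindcasting applies each replicate model to a past stage's climate with the
*training* feature rescale and no clamping, so conditions outside the
calibration range extrapolate; MESS maps flag exactly where that happens.
Replicates are combined by the cell-wise median.

## Grid conventions and numerical choices

* Cells are half-open: a point on a boundary belongs to the cell
  north/east of it; longitude wraps at the dateline; no cell straddles the
  equator. Latitudes report as cell-center values (x.5° at 1°).
* Bathymetry aggregation preserves the *minimum* depth among marine fine
  cells, so oceanic islands survive coarsening; an all-land block stays
  land.
* The depth filter is strict (`0 < depth < 200` m).
* Bilinear regridding clamps poleward of the outermost coarse rows rather
  than inventing polar values, and propagates missingness: any target cell
  whose 4-point stencil touches a missing (land) coarse cell starts
  missing and is then filled by iterated 3 × 3 focal means over the mask.
  Iteration to closure (rather than a single pass) guarantees every mask
  cell has predictors; a single-pass mode exists for comparison. If a mask
  cell can never be reached the fill errors, listing the cells.
* Binary thresholds: LTP is the minimum suitability over training
  presences; MaxSSS scans all distinct observed scores and breaks ties
  toward the lowest (most inclusive) threshold. Both are computed on the
  calibration stage's median map and applied unchanged to all hindcasts,
  since past truth is unavailable for re-thresholding.
* The Boyce index uses 101 overlapping windows of width one tenth of the
  score range (a common published default; both are configurable). Under
  the null the single-draw index has a standard deviation of ~0.27 because
  neighbouring windows share cells — single draws are noisy by
  construction, so tests assert its null *mean*.
* The one-sample comparison of null percentages against the observed
  fossil success is a Wilcoxon *signed-rank* test (the conventional
  one-sample form of a rank test), one-sided; the two-sample comparison of
  suitability values is a Mann–Whitney rank-sum test, one-sided. Both use
  exact null distributions for small untied samples (signed-rank
  $n \le 25$, rank-sum $\min(n,m) \le 10$) computed by generating-function
  convolution, and tie-corrected normal approximations with continuity
  correction otherwise.
* Spherical cell areas are exact:
  $A(\phi) = R^2\,\Delta\lambda\,(\sin\phi_{top} - \sin\phi_{bot})$ with
  $R = 6371$ km; binned areas sum to the global area by construction.
* Reef-zone uncertainty intervals are the 2.5/97.5 percentiles of
  per-replicate poleward extremes (the population behind such quantiles is
  ambiguous in principle — replicates vs. stages — and replicates are the
  default here because they isolate model uncertainty at fixed geography).
* All randomness flows from one top-level seed through named substreams
  (`derive_seed(seed, "hsm")`, `derive_seed(seed, "null", stage)`, ...), so
  identical configurations give byte-identical outputs and components can
  be re-run in isolation.

## The synthetic world

The generator emulates, at desk scale, the statistical structure of the
real inputs:

* **Bathymetry** (0.5° native): continents are smooth rectangular plateaus
  with linear shelf ramps reaching 200 m over a configurable width
  (default 6°), then a steep slope to a 4000 m abyss. A per-stage sea-level
  offset shifts the whole field, so a sea-level fall demonstrably shrinks
  the shallow shelf — the class of behaviour behind major shelf-area drops
  across stage boundaries. Continents may drift between stages.
* **Climate** (2.5° × 3.75° native, mirroring a coupled climate model's
  grid): mean-maximum SST follows
  $T_{eq} + g_t - \Delta T \sin^2\phi$ plus smoothed Gaussian anomalies;
  the seasonal minimum sits $4 + s|\sin\phi|$ °C below it. Three choices
  depart from the simplest zonal construction, and matter: (1) the anomaly
  patches are *stationary across stages* (geography-locked warm pools and
  gyres), with the stage signal carried by the global offset $g_t$;
  (2) the minimum-SST layer co-varies with the maximum layer (a warm pool
  is warm year-round), with only a small independent component
  ($\sigma/4$); (3) insolation declines as $\sin^4\phi$ — nearly flat
  through the tropics, as real seasonal-extreme insolation is — plus
  stationary cloud-like anomalies. Without these, all four predictors are
  deterministic functions of latitude, any latitude proxy discriminates
  presences perfectly, and no presence-background method could identify
  minimum SST as the limiting variable — the recovery checks would be
  vacuous. Ocean-model realism is emulated by masking climate cells whose
  center lies on land, which exercises the regrid-then-gap-fill path
  end-to-end.
* **Truth species**: suitability is the product of logistic responses in
  minimum SST (midpoint 18 °C, width 0.5 °C) and minimum insolation
  (midpoint 120 W m⁻², width 15 — binding only at high latitudes), on mask
  cells and zero elsewhere. Only two of the four predictors matter; the
  other two are informative-but-redundant, so the tests exercise the
  model's tolerance of correlated predictors.
* **Sampling**: modern presences are drawn without replacement with
  probability proportional to truth (default 500 cells). Fossils are drawn
  per stage proportional to truth, thinned in the Southern Hemisphere by
  the bias parameter $\rho$ (default 0.5, emulating preferential Northern
  Hemisphere sampling), and their stage age intervals are widened by
  uniform jitter (default 2 Myr per side) so the >50%-overlap binning rule
  is genuinely exercised; a configurable fraction of "cold outliers" below
  the SST limit is available for false-negative experiments (default 0).

What the generator does **not** emulate: plate kinematics, ocean
circulation, upwelling and nutrient fields, preservation/rock-record
biases beyond the hemispheric thinning, and within-stage climate
variability. Passing tests therefore demonstrate that the *machinery* is
correct and that the method recovers a known truth under its own
assumptions — they say nothing about whether those assumptions hold for
any real ocean.

## What the tests show

The suite (and `scripts/acceptance.R`) runs at these problem sizes, chosen
to keep a full desk-scale run in minutes while leaving the statistics
well-powered: a 5-stage world on the 1° working grid (~5200 shallow cells),
500 presences, 10,000 background draws, 20 bootstrap replicates, 1000
random point sets per stage; the orchestration demo uses a 3-stage, 2°
world with 3 replicates.

Highlights:

* the fitted objective matches generic-optimiser minima on tiny instances,
  and moment matching holds at $\beta = 0$;
* rank statistics (AUC, Mann–Whitney U, signed-rank tails) equal
  exhaustive enumeration;
* with fossils drawn from past truth, every stage with ≥ 10 localities
  rejects the random-point null at $p < 0.05$ (observed $p$ far smaller),
  while the null mean itself converges to the suitable fraction of the
  mask — the null model is calibrated, not conservative;
* the hindcast LTP reef zone tracks the truth species' own range limit
  (the poleward-most cell whose truth suitability reaches the
  least-training-presence level) within 2° of latitude per stage and
  hemisphere; a +4 °C stage moves the reef zone poleward, and a monotone
  cooling sequence at fixed geography moves the Northern Hemisphere
  centroid monotonically equatorward. The comparison is made against the
  truth's range limit rather than the raw 18 °C isotherm because the truth
  species itself occupies the logistic tail below 18 °C, so the LTP
  boundary legitimately sits poleward of the 0.5-level isotherm — matching
  against the isotherm would conflate that tail with model error.

## Known limitations

* The L1 rule `β·s_j/√m` is a simplification of reference-Maxent default
  regularisation; absolute suitability values are not comparable to that
  implementation's, though thresholds and ranks behave equivalently.
* The entropy-based logistic output is uncalibrated in the probabilistic
  sense (see above); comparisons should stay on ranks, thresholds, or
  geographic summaries.
* Quadratic features make extrapolated responses eventually decrease in
  any variable; hindcasts far outside the calibration range should always
  be read together with the MESS map.
* Grids are geographic lat–lon only; there is no plate-rotation engine —
  fossil inputs must already carry palaeocoordinates.
* With default settings the background (10,000 draws) exceeds the synthetic
  mask (~5200 cells) and is drawn with replacement; this mirrors the
  fixed-budget background convention and is logged when it happens.
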