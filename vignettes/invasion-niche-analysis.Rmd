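---
title: "Modelling invasion niches: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling invasion niches: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `nicheshift`, the
assumptions behind them, the tunable parameters that matter, and the
design choices we made where the methods literature leaves room. It is a
methods document: every empirical statement about the package's behavior
is one that the test suite or `scripts/acceptance.R` computes.

## The scientific problem

When a species invades a new region, two questions matter for risk
assessment: *where else could it establish*, and *has its realized
climatic niche shifted* between the native and invaded ranges? The
package answers both from presence-only occurrence records and gridded
climate:

1. a presence-background maximum-entropy model maps relative climatic
   suitability and identifies the climatic drivers;
2. an ordination-based (PCA-env) comparison of occurrence densities in
   climate space quantifies niche overlap (Schoener's D), tests it
   against randomization nulls, and decomposes it into expansion,
   stability and unfilling;
3. paired regional and global model predictions classify occurrences
   into invasion stages (stabilizing, colonization, adaptation, sink).

Because real multi-source occurrence compilations and ~1-km climate
layers are large external downloads, the package ships a seeded
virtual-species generator that reproduces the *structure* of such a
study — paired landscapes, a known suitability function, a controllable
niche shift, spatially biased sampling — so every estimator can be
validated by parameter recovery.

## Climate predictors

`derive_bioclim()` computes the 19 standard bioclim summaries from
monthly minimum/maximum/mean temperature (degrees C) and precipitation
(mm); `degree_days()` adds a growing-degree-day layer (base 10 degrees C
by default). Conventions, chosen once and fixed:

* quarters are all twelve 3-consecutive-month windows with December to
  February wrap-around; the extreme window is selected per cell, ties
  broken by the earliest start month;
* `bio3 = bio2 / bio7 * 100` (0 where `bio7 = 0`) and
  `bio4 = 100 * SD` of the monthly means (sample SD);
* `bio15 = 100 * SD(prec) / (1 + bio12/12)`, the usual offset form that
  tolerates arid cells;
* degree-days use calendar month lengths of a 365-day year:
  `sum(days_m * max(0, tmean_m - base))`. The monthly-mean approximation
  is deliberate: sub-monthly degree-day models need daily data the rest
  of the pipeline does not.

Collinearity screening (`prune_collinear()`) is a greedy pass over a
priority-ordered variable list that retains a variable only when its
absolute Pearson correlation with everything already retained is below
0.80 (strictly; a pair at exactly 0.80 is collinear). The default
priority puts the ecologically interpretable contributors first
(degree-days, precipitation of the driest quarter, and so on).

Rasters are exchanged as single-band ESRI ASCII grids (plain text, one
file per variable, shared grid); in memory they are matrices with a
lower-left origin and square cells, `NA` as nodata. All distance and
kernel computations on geographic coordinates go through a World
Cylindrical Equal Area projection so areas are preserved.

## Occurrence preparation

`dedupe_to_grid()` keeps one record per climate cell (first by input
order — a stable, reproducible tie-break). `spatial_thin()` enforces a
minimum pairwise distance with the usual greedy heuristic: repeatedly
remove a record among those with the most too-close neighbours, chosen
at random under the seed. The thinning distance is a study decision, not
a constant of nature; the default is 10 km, appropriate for ~1-km grids
with clustered, road-biased sampling. Every retained set is verifiable:
the tests re-check all pairwise distances by brute force.

`bias_surface()` builds a Gaussian kernel density of the (thinned)
occurrences — the standard proxy for survey effort when collections come
from museums and opportunistic records — rescaled to a maximum of 1 with
a floor of `1e-6`. The default bandwidth is twice the thinning distance.
`sample_background()` draws background cells without replacement from
the accessible-area mask, with probabilities proportional to the bias
surface when one is supplied. We weight the *selection* of background
points rather than re-weighting them inside the likelihood; both paths
are supported (`maxent_sdm(bg_weights=)`), but weighted selection is the
default because it matches how bias surfaces are used in standard
MaxEnt-style workflows.

## The maximum-entropy model

`maxent_sdm()` fits a Gibbs distribution over the background,
maximizing the penalized presence log-likelihood

$$\frac{1}{m}\sum_{i \in \text{presences}} \eta(x_i) - \log Z_w
  - \beta \sum_j s_j |\lambda_j|, \qquad
  \eta(x) = \sum_j \lambda_j f_j(x),\quad
  Z_w = \sum_{\text{background}} w(x) e^{\eta(x)}.$$

Features are built on variables min-max scaled to [0, 1] over the
background (the same bounds clamp projections): linear, quadratic,
pairwise product, and forward/reverse hinge ramps at evenly spaced
interior knots (50 per variable and direction by default; the pipeline
uses 20 to keep the design matrix small). The per-feature penalty
scales $s_j$ follow the published MaxEnt default tables — interpolated
by presence sample size per feature class, multiplied by the feature's
presence-sample SD (floored at $1/\sqrt{m}$) over $\sqrt{m}$ — and
$\beta$ multiplies them uniformly; the candidate grid sweeps
feature-class sets and $\beta$ exactly as an applied study would
(defaults: linear+quadratic+hinge at 1.5, linear+quadratic+product at
2.5, all four at 2.5).

The optimizer is monotone proximal-gradient descent (soft-thresholding
step) with Barzilai–Borwein step sizes and backtracking, so the
penalized objective is non-increasing by construction and the trace is
asserted in the tests. Convergence is declared when the objective
changes by less than `tol` (default `1e-7`, capped at 5000 iterations;
failing that is an error that carries the trace). For analyses that need
stationarity beyond the objective plateau — e.g. verifying the maxent
moment-matching property $E_q[f_j] = \bar f_j^{\text{presence}}$ — the
control list exposes `gtol`, a bound on the proximal-gradient residual.

Outputs: `predict(type = "raw")` is the normalized Gibbs density over
the training background; `type = "logistic"` applies the standard
entropy transform $s = e^H \tilde q/(1 + e^H \tilde q)$ (fixed default
prevalence 0.5), bounded in (0, 1) and rank-equivalent to the raw
output. Raster prediction clamps variables to the training bounds
(idempotently) and propagates nodata.

Model selection: `aicc_rank()`/`rank_candidates()` score candidates by
AICc with the log-likelihood of the raw distribution renormalized over
the full landscape and `k` = number of nonzero coefficients; candidates
with `k >= n - 1` are excluded, as are candidates whose marginal
response curves have more interior local maxima than the configured
screen (default 2 in the pipeline) — the "biologically nonsensical
curve" filter expressed as a count rather than a judgement call.
Variable contributions are permutation importance (permute one
variable's values across presences and background jointly, measure the
drop in training gain, normalize to 100%); we prefer this to the
optimizer-path attribution of the original Java implementation because
it is estimator-agnostic and reproducible, and the jackknife
(only-variable / without-variable refits) is available where the
gain decomposition is wanted.

## Evaluation

`evaluate_sdm()` reports k-fold cross-validated AUC (default 10-fold;
background points stand in for absences, so AUC is a relative ranking
score, not a classification accuracy), omission-based thresholds (the
0% and 10% order statistics of training presence scores) with held-out
sensitivities, and the partial-ROC bootstrap. Partial ROC compares the
area under the (proportion of landscape predicted, sensitivity) curve,
restricted to sensitivity at least `1 - E`, against the area under the
diagonal over the same interval; ratios above 1 beat random. Bootstrap
defaults — 50% of test points resampled, 1000 replicates — follow common
usage of the method; the p-value is the fraction of replicate ratios at
or below 1. With test points on raster cells the "perfect model" limit
of the ratio is `2/(1 + a)` with `a` the presence-cell fraction, which
converges to 2 as the landscape grows; the acceptance suite checks this
at `a = 0.001`.

## PCA-env niche overlap

`niche_overlap()` fits a correlation-matrix PCA on the *pooled
backgrounds* of the two ranges being contrasted (variables mix degrees
C, mm and degree-days, so standardization is not optional), projects
occurrences and backgrounds onto PC1–PC2, and builds kernel-smoothed
occupancy grids on a shared 100 x 100 frame. The occupancy of a cell is
the occurrence density divided by the background (availability) density,
renormalized to sum to 1 — the availability correction that lets ranges
with different climates be compared. Overlap is Schoener's
$D = 1 - \tfrac12\sum|o_1 - o_2|$.

Two numerical guards matter and are worth stating plainly:

* **Availability floor.** Kernel densities are positive everywhere, and
  in the far tails the occurrence and background kernels decay at
  different rates, so their ratio can explode on cells that carry no
  real availability. Cells with background density below `1e-4` of its
  maximum are therefore treated as unavailable (configurable via
  `occupancy_grid(env_floor=)`). With a much smaller floor the
  occupancy mass migrates to artifact cells and D stops responding
  monotonically to a simulated shift; with this one it behaves.
* **Presence mask for dynamics.** For expansion/stability/unfilling a
  niche is "present" on the smallest set of highest-occupancy cells
  holding 95% of its mass. A value-based zero threshold cannot work on
  smoothed surfaces (nothing is exactly zero); the mass-based rule keeps
  the subset and disjoint identities exact and matches the intersection
  convention of the invasion-dynamics literature.

The equivalency test pools and reassigns occurrences (group sizes
preserved) and rebuilds both grids per replicate; the similarity test
rigidly translates one range's occurrence cloud to a random cell of its
own background support. Both report both tails with the add-one
estimator `p = (count + 1)/(reps + 1)`; 100 randomizations by default.
The methods source is silent on which of the two tests its "100
randomizations" refers to, so both are implemented and reported.
Background kernel surfaces are computed once and reused across
replicates — the randomizations only move occurrences.

Dynamics indices are computed within the analogue climate (cells above
the availability floor in *both* backgrounds): expansion is the invasive
occupancy mass where the native niche is absent (as a fraction of the
invasive analogue mass), stability its complement, unfilling the mirror
image for the native niche; the centroid shift is the difference of
occupancy-weighted mean PC positions.

## Invasion stages

`classify_stage()` is a pure function of the regional (invaded-range
fit) and global (native+invasive fit) predicted suitabilities and a
threshold `tau` (default 0.5, with "high" meaning `>= tau` so the four
quadrants partition the unit square): both high = stabilizing, global
high only = colonization, regional high only = adaptation, both low =
sink. `classify_stage_raster()` maps cells with integer codes 1–4 and
returns category counts.

## The virtual-species generator

`generate_invasion_study()` builds three landscapes (native, a focal
invaded region, a second invaded region) of monthly climate driven by
four seeded band-limited random fields (sums of sinusoids — chosen over
FFT random fields to keep the generator dependency-free and exactly
reproducible across platforms): thermal level, continentality (diurnal
range and seasonal amplitude), precipitation level and precipitation
seasonality. Monthly cycles peak in July; `tmin <= tmean <= tmax` and
non-negative precipitation hold by construction. True suitability is a
logistic quadratic bowl around a niche optimum in chosen bioclim
variables (defaults: annual mean temperature 20 degrees C with 2 degrees
breadth, annual precipitation 1200 mm with 300 mm breadth). Occurrences
are sampled with probability proportional to suitability times an
optional bias field and jittered within their cell.

The niche shift is expressed in native-background standard deviations:
the invaded optimum equals the native optimum plus `delta_sd` SDs along
a unit direction, and the configured optimum is their midpoint so both
sit symmetrically inside the available climate (otherwise large shifts
push an optimum off the climate manifold and truncate the occurrence
cloud, which would confound parameter recovery with availability
artifacts). The second invaded range defaults to a 1.5-times-larger
shift, mirroring a system where the further invasion shifted more. The
truth record keeps the per-range optima, the shift vectors in variable
units, and the native SDs, which is exactly what is needed to score
recovery: the projected true optimum displacement in the fitted PC plane
is compared against the measured occupancy-centroid shift.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: dispersal limitation and spatial
aggregation beyond sampling bias, interactions among climate variables
other than through the four latent fields, taxonomic/georeferencing
error, and non-analogue climate beyond what independent landscape draws
produce. Recovery results on virtual species are a validation of the
estimators, not a claim about any particular organism.

## Pipeline and problem sizes

`run_pipeline()` chains everything under one configuration with a single
master seed; each stage derives its own sub-seed from a stable string
hash, so stages are independently reproducible and the emitted report
(JSON plus text summary) carries a content hash that is identical across
reruns. Desk-scale defaults, chosen so a full run takes a few minutes on
one CPU and stated here as the package's own study sizes: 200 x 200-cell
landscapes, 250 presences per range, `delta_sd = 1`, 10,000 background
points per range (the fitting functions accept the 50,000 used in
large-scale studies; the generator's landscapes simply have fewer
cells), 20 hinge knots, 10-fold cross-validation, 1000 partial-ROC
replicates, 100 overlap randomizations at a 100 x 100 grid. The
acceptance tests run the null-calibration study at 99 randomizations and
200 replicates and the parameter-recovery sweep on 100 x 100 landscapes
with 200 presences over 20 seeds per shift level.

## Known limitations

* AUC on presence-background data is bounded away from 1 by the true
  prevalence of suitable climate; on the synthetic landscapes (where a
  large fraction of cells is genuinely suitable) cross-validated AUC
  sits well below what sparse-range empirical studies report, and the
  two are not comparable.
* The logistic output's 0.5-prevalence convention is a display
  transform; thresholds (`tau`, omission thresholds) inherit its
  arbitrariness and should be read as relative.
* The equivalency null reassigns occurrences between ranges, which
  conflates niche and availability differences when backgrounds differ
  strongly; the similarity test is the sharper tool in that case.
* Hinge-rich candidate models on small presence samples can be excluded
  wholesale by the AICc screen (`k >= n - 1`); that is by design.
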