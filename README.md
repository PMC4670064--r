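# nicheshift

Climate-based invasion risk analysis for presence-only occurrence data:
presence-background maximum-entropy distribution modelling, PCA-based
realized-niche-shift quantification, and invasion-stage classification,
validated end to end on simulated virtual species.

## Who this is for

Ecologists and invasion biologists who have georeferenced presence
records of a species in its native and invaded ranges plus gridded
monthly climate, and who want to (a) map relative climatic suitability
and its drivers, (b) test whether the realized climatic niche shifted
during invasion, and (c) hypothesize the invasion stage of each
population. The package implements the full workflow as ordinary R
functions with classed results, so every step is scriptable and
reproducible from one seed.

## The models at its core

**Presence-background maximum entropy.** With features
`f_j` (linear, quadratic, product, hinge expansions of the scaled
climate variables), `maxent_sdm()` maximizes the penalized presence
log-likelihood

    (1/m) Σ_presences η(x) − log Z_w − β Σ_j s_j |λ_j|,
    η(x) = Σ_j λ_j f_j(x),   Z_w = Σ_background w(x) exp(η(x)),

a lasso-regularized Gibbs distribution over the background; `s_j` are
the standard per-feature-class regularization scales and `β` the global
multiplier. Fitting is monotone proximal-gradient descent; outputs are
the raw normalized density and the logistic suitability
`e^H q̃ / (1 + e^H q̃)` in (0, 1). Candidate feature/β settings are
ranked by AICc (`rank_candidates()`), and models are evaluated by
10-fold cross-validated AUC, partial-ROC bootstrap ratios and
omission-based sensitivities (`evaluate_sdm()`).

**Niche overlap in environmental space.** `niche_overlap()` projects
occurrences and backgrounds of two ranges onto the first two axes of a
correlation PCA of the pooled backgrounds, builds availability-corrected
kernel occupancy surfaces, and reports Schoener's

    D = 1 − ½ Σ_cells |o1 − o2|  ∈ [0, 1],

with equivalency and similarity randomization tests, niche
expansion/stability/unfilling within analogue climate, and the niche
centroid shift in PC units.

**Invasion stages.** `classify_stage()` places each occurrence (or map
cell) in one of four quadrants of the (regional, global) predicted
suitability plane: stabilizing, colonization, adaptation, sink.

**Virtual species.** `generate_invasion_study()` simulates paired
native/invaded landscapes of monthly climate, derives the 20 bioclim
predictors (`derive_bioclim()`, `degree_days()`), defines a known
suitability function with a controllable niche shift (in
background-SD units), and samples optionally biased occurrences — the
ground truth used by the test suite to verify parameter recovery.

## Worked example

```r
library(nicheshift)

# a small synthetic invasion study with a known 2-SD niche shift
cfg <- virtual_species_config(nrow = 80, ncol = 80, n_presences = 150,
                              delta_sd = 2, seed = 42)
study <- generate_invasion_study(cfg)

# prepare occurrences and background for the focal invaded range
rg <- study$ranges$invasive_conus
occ <- spatial_thin(dedupe_to_grid(rg$occurrences, rg$predictors[[1]]),
                    min_dist_km = 5, seed = 1)
bg <- sample_background(rg$mask, n = 4000, seed = 2)
env_occ <- extract_env_values(occ$records, rg$predictors)
env_bg <- extract_env_values(xy_from_cell(rg$mask, bg$points$cell),
                             rg$predictors)
vars <- c("bio1", "bio2", "bio4", "bio12", "bio15")

fit <- maxent_sdm(env_occ[, vars], env_bg[, vars], classes = "lqh",
                  beta = 1.5, n_hinge_knots = 20)
fit
#> Maximum-entropy presence-background model
#>   features: linear+quadratic+hinge (210 total, 11 with nonzero coefficient)
#>   beta = 1.5, presences = 52, background = 4000
#>   penalized log-likelihood = 0.5337, entropy = 7.7608 (225 iter)
```

The model kept 11 of 210 features under the lasso penalty; the entropy
feeds the logistic output, and `predict(fit, stack)` projects
suitability over any aligned raster stack with training-range clamping.

```r
# same preparation for the native range, then the PCA-env contrast
nat <- study$ranges$native
occ_nat <- extract_env_values(nat$occurrences$records, nat$predictors)
bg_nat <- extract_env_values(
  xy_from_cell(nat$mask, sample_background(nat$mask, 4000, seed = 3)$points$cell),
  nat$predictors)

ov <- niche_overlap(occ_nat[, vars], env_occ[, vars],
                    bg_nat[, vars], env_bg[, vars], reps = 99, seed = 4)
ov
#> PCA-env niche overlap
#>   Schoener's D = 0.142
#>   equivalency test:  p(lower) = 0.950, p(higher) = 0.060 (99 reps)
#>   similarity test:   p(lower) = 0.920, p(higher) = 0.090 (99 reps)
#>   expansion = 0.830, stability = 0.170, unfilling = 0.684
#>   centroid shift = (0.46, -1.73) PC units
```

The simulated 2-SD shift shows up exactly as it should: low overlap
(D = 0.14), 83% of the invaded niche outside the native one
(expansion), and a centroid displacement of about 1.8 PC units
(`sqrt(0.46² + 1.73²)`) against a true projected shift of 2 dampened by
availability at the landscape edges. Classifying the invaded-range
occurrences against the paired global (native + invasive) model:

```r
glob <- maxent_sdm(rbind(occ_nat[, vars], env_occ[, vars]),
                   rbind(bg_nat[, vars], env_bg[, vars]),
                   classes = "lqh", beta = 1.5, n_hinge_knots = 20)
table(classify_stage(predict(fit, env_occ[, vars]),
                     predict(glob, env_occ[, vars])))
#>  stabilizing colonization   adaptation         sink
#>            1            1           37           13
```

With a strongly shifted niche, most invaded-range populations sit in
the regional-adaptation quadrant — the regional model rates their
climate highly while the global model, anchored by the native range,
does not.

The whole analysis — occurrence prep, candidate fitting and selection,
evaluation, all four range contrasts, stage maps, JSON report — runs as
one seeded pipeline:

```r
res <- run_pipeline(default_pipeline_config(seed = 1), out_dir = "out")
```

A thin command-line wrapper is included at
`inst/scripts/run_pipeline.R`.

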