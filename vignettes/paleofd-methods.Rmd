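---
title: "Methods: linking glacial history to plant functional diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking glacial history to plant functional diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Continental-scale patterns of plant functional diversity (FD) — how much of
trait space a regional assemblage occupies, and how spread out its species
are within it — reflect both contemporary environment and the legacy of
late-Quaternary climate change. Since the Last Glacial Maximum (LGM, roughly
21,000 years ago), recolonization from glacial refugia has been
dispersal-limited and climate has been regionally more or less stable;
both processes can leave lasting imprints on which trait combinations occur
where. `paleofd` implements a complete, testable pipeline for quantifying
those imprints: per-grid-cell FD metrics with null-model standardization,
historical predictors (climate-change velocity, accessibility to glacial
refugia), and exhaustive spatial-autoregressive multimodel inference that
weighs historical against contemporary predictors.

Because atlas-scale distribution data and paleoclimate model ensembles are
large external resources, the package ships a first-class synthetic-data
generator that reproduces the statistical structure those data are assumed
to have. Every stage of the pipeline is validated against that generator
with known ground truth.

# Trait preparation and imputation

Four continuous ecomorphological traits are used: specific leaf area
(cm² g⁻¹), seed mass (mg), maximum stem height (m) and stem/wood density
(kg m⁻³), plus a categorical growth form (fern, graminoid, forb, shrub,
tree, climber). Trait distributions are lognormal, so all analysis happens
on log10-transformed values z-scored to mean 0 and SD 1 over observed
entries (`log_standardize()`; the population-SD convention is used and the
transform metadata makes the mapping exactly invertible).

Compiled trait databases have large gaps — around 40–55% missing per trait
is typical. `mice_impute()` fills them by chained equations on the
standardized log scale: each incomplete trait is regressed on the other
three traits, growth-form indicators, and a genus-mean covariate of the
target trait (the "evolutionary constraint"). Design choices, made where
the method family leaves them open:

* **Predictive mean matching (PMM) with k = 5 donors.** Draws are observed
  values of the k candidates whose predictions are closest, so imputations
  always stay inside the observed support. Coefficients are redrawn from
  their approximate posterior each sweep (type-1 PMM), which propagates
  estimation uncertainty into the imputations.
* **Genus means as covariates, not per-genus fixed effects.** Many genera
  are monotypic; fixed effects would be unidentifiable. Genus means are
  computed from originally observed values only (leak-free and stable
  across sweeps), with growth-form-mean fallback for genera lacking
  observations.
* **Convergence** is declared when the mean absolute change of imputed
  values between sweeps drops below 1e-3 (standardized units), with a cap
  of 20 sweeps. With PMM the chain keeps resampling donors, so the cap is
  usually what stops it; the per-sweep change trace is returned so users
  can inspect mixing.
* **m = 10 independent chains** by default, giving m completed tables whose
  downstream spread measures imputation uncertainty. Observed cells are
  bit-identical across replicates by construction.

Known limitation: with ~50% missingness in *all* traits and only weak
inter-trait correlation, any chained-equations scheme attenuates
cross-trait correlations in individual replicates (we verified the same
behaviour in an independent reference implementation). The replicate-mean
completed data preserves allometric correlations well when traits are
informative about one another; with weakly correlated traits it does not,
and results involving trait covariation should be read accordingly.

# Functional diversity metrics

Per grid cell, using the standardized log traits of the species present:

* **Functional richness** is the volume of the convex hull in the d = 4
  dimensional trait space. The hull volume is computed by an exact
  supporting-hyperplane enumeration (compiled code): every d-subset of
  species spanning a hyperplane with all species on one side is a
  supporting hyperplane; unique hyperplanes are collected and the facet
  (d−1)-volumes are obtained recursively after projecting onto an in-plane
  orthonormal basis. No "joggling" perturbation is applied: assemblages
  with fewer than d + 1 species, or affinely degenerate ones, are reported
  as undefined (`NA`) rather than silently perturbed, and such cells are
  dropped from functional-richness regressions. The implementation
  reproduces analytic solids (unit tetrahedron 1/6, unit 4-cube 1) to
  better than 1e-9 and matches an independent qhull-based computation to
  1e-10 on random point sets.
* **Functional dispersion** is the mean Euclidean distance of species to
  the assemblage trait centroid — 0 exactly when all species share one
  trait vector.
* **Univariate range and dispersion** (max − min, population SD) per trait
  complement the multivariate metrics.

**Null model and SES.** To separate trait structure from species richness,
each occurrence matrix is randomized preserving every cell's richness
exactly: a cell with k species receives k species drawn uniformly without
replacement from the full pool (`randomize_occurrence()`). Uniform species
weights are the literal reading of richness-preserving randomization;
frequency-preserving swap algorithms are deliberately not the default.
The standardized effect size is (observed − null mean)/null SD with the
sample-SD (n−1) convention. Under its own null the SES is approximately
standard normal; the test suite verifies |mean| < 0.1 and SD within
[0.85, 1.15] at 200 cells × 500 randomizations.

# Historical predictors

* **Ensemble averaging** (`ensemble_mean()`): glacial surfaces from
  multiple climate models are combined cellwise (no-data ignored) before
  any derived quantity is computed.
* **Change-factor downscaling** (`change_factor_downscale()`): coarse-model
  anomalies — additive for temperature, multiplicative (ratio, denominator
  floored at 0.1 mm) for precipitation — are interpolated bilinearly
  between coarse cell centres and applied to a fine present-day baseline.
  Constant change factors are reproduced exactly.
* **Growing degree-days** (`growing_degree_days()`): accumulated monthly
  warmth above a 5 °C base on a 365-day calendar, °C·day.
* **Glacial refugia** (`refugia_mask()`): cells jointly satisfying
  GDD ≥ 800 °C·day, coldest-month mean temperature ≥ −15 °C, and
  June–August precipitation ≥ 50 mm (boundaries inclusive). The
  coldest-month threshold is worth a note: the published criterion for
  cool-temperate trees is a *cold-tolerance* bound, and a +15 °C reading
  would exclude virtually all of Europe; the package defaults to −15 °C
  and exposes the threshold as a parameter. "Summer" is June–August, the
  Northern-Hemisphere convention.
* **Climate velocity** (`climate_velocity()`): the temporal trend (absolute
  LGM-to-present anomaly per decade, endpoints only — intermediate
  oscillations such as the Bølling–Allerød are not resolved) divided by the
  local spatial gradient of the present-day surface. The gradient is
  Horn's 3×3 slope magnitude (edge cells use replicated neighbours),
  floored at 1e-5 units·km⁻¹ so flat terrain yields large but bounded
  velocities; floored cells are flagged. Velocity is invariant to adding a
  constant to both epochs and doubles when the anomaly doubles. A log10
  companion grid is returned for the usual lognormal handling.
* **Accessibility** (`accessibility()`): for each focal cell, the sum of
  inverse Euclidean centroid distances (projected km) to every refugial
  cell; a refugial focal cell contributes a self-term at half the cell
  size. Summation is over refugial *cells*, the literal per-cell reading,
  rather than over merged refugial regions.

Raster I/O uses the ESRI ASCII grid format (plain text, no-data honoured);
the synthetic grids are planar, so distances are Euclidean.

# Spatial regression and multimodel inference

**Weights.** Each cell is linked to its first (nearest) neighbour; the
adjacency is symmetrized (i ~ j if either is the other's nearest
neighbour, which guarantees no isolated node) and row-standardized.

**SAR-error model.** FD responses are related to predictors through
y = Xβ + u, u = λWu + ε. The likelihood is concentrated over λ and
maximized on (−0.999, 0.999) by bounded scalar optimization; for each λ,
β and σ² follow from least squares on the spatially filtered system. The
log-determinant term uses the eigenvalue spectrum of W (real, because the
row-standardized W is similar to a symmetric matrix), precomputed once per
weights object; the test suite checks it against a sparse-LU computation.
With λ fixed at 0 the fit is ordinary least squares exactly. The AIC
parameter count is p + 2 (coefficients including intercept, plus λ and
σ²), kept uniform so it cancels in model comparison. Response and
predictors are z-scored before fitting, making coefficients standardized;
skewed predictors (annual precipitation, velocities) are log10-transformed
first.

**Model set.** All combinations of {absent, linear, unimodal
(linear + quadratic)} per predictor are enumerated — 3^p models including
the intercept-only one, in deterministic lexicographic order, with an
optional cap on predictors per model. Quadratic terms are squares of the
standardized predictor, not orthogonalized; the exhaustive-AIC design
tolerates the induced collinearity. (Atlas-scale analyses of this design
have reported model counts — 28,672 over 12 predictors — that do not
correspond to the full factorial, which is 3¹² = 531,441; `paleofd`
defines the set as the complete factorial with an optional cap and leaves
that discrepancy documented rather than resolved.)

**Inference.** Akaike weights w = exp(−Δ/2)/Σexp(−Δ/2); per-predictor
relative support W_AIC is the sum of weights of models containing the
predictor; model-averaged standardized coefficients are conditional
(renormalized over containing models — the zero-filled variant is a
deliberate non-default); single-predictor explained variance is the
Nagelkerke pseudo-R² of the unimodal single-predictor fit against the
intercept-only SAR-error null (so spatial structure is in both models and
the statistic isolates the predictor's contribution). Everything is run
per imputation replicate and pooled as mean with 2.5/97.5 percentile
intervals; since summary scores (not coefficient standard errors) are
pooled across imputed datasets, Rubin's rules are not needed. Partial residuals
r + b·x, with r the trend residuals of the all-predictor unimodal model,
display each historical predictor's effect with everything else
statistically controlled.

**Dutilleul-corrected correlation.** Pairwise predictor correlations on
autocorrelated surfaces need an effective sample size. Spatial correlation
matrices of both variables are estimated from distance-class Moran
coefficients; the corrected degrees of freedom follow Dutilleul's
modified t-test, M = 1 + tr(BΣ̂x)·tr(BΣ̂y)/tr(BΣ̂xBΣ̂y) with B the centring
matrix. On white noise the effective n stays within a few percent of n; on
strongly autocorrelated independent isotropic fields the corrected test
holds its 5% level (~3–7% empirically) while the naive test rejects 30–50%
of the time. The correction assumes distance-dependent (stationary,
isotropic) autocorrelation; processes whose correlation follows network
topology rather than distance (e.g. an SAR process on a sparse
nearest-neighbour graph) violate that assumption and remain
under-corrected.

# The synthetic study system

`synthetic_config()` fixes the conditions the validation suite runs under;
the defaults are chosen once, as a plausible miniature of an atlas-scale
European analysis, and the tests run against them unchanged:

* 20×20 grid of 50 km equal-area cells; 300 species in 60 genera.
* Traits lognormal on the log10 scale (means 2.2, 0.3, −0.2, 2.6; SDs 0.3,
  1.0, 0.6, 0.15 for SLA, seed mass, height, density), with a genus-level
  variance share of 0.15 drawn with the same correlation matrix as the
  species level, so the marginal inter-trait correlation equals the
  configured `trait_corr` exactly. Growth forms attach to genera and shift
  log height only (so they inform imputation without distorting the
  configured trait correlations).
* Missingness is injected completely at random (MCAR) at the atlas-style
  rates (SLA 50%, height 53%, seed mass 50%, density 42%) — the simplest
  mechanism under which chained-equations imputation is unbiased.
* Monthly present-day climate combines a latitudinal gradient, seeded
  smooth "topography" textures, and a seasonal cycle whose amplitude grows
  eastward (continentality); the glacial surface subtracts an anomaly
  growing from 6 °C (south) to 12 °C (north) with its own texture and
  scales precipitation by ~0.7 with mild spatial variation. The distinct
  textures matter: with purely latitudinal gradients every derived
  predictor collapses onto latitude (pairwise |r| up to 0.98), whereas the
  analysis this package supports presumes a predictor set without strong
  multicollinearity; under the defaults most pairwise correlations are
  below 0.6.
* Occurrences: per-cell richness is a deterministic monotone rescaling of
  a designated predictor (accessibility by default) into
  `richness_range` = (10, 60); species are drawn without replacement with
  Gaussian inclusion weights exp(−0.5·s·|z_filter|·z_height²), so trait
  filtering vanishes where the filter predictor is average and narrows
  trait space where it is extreme.
* Recovery responses follow the SAR-error process exactly:
  u = (I − λW)⁻¹ε solved directly, λ = 0.5, ε SD 1, standardized effects
  accessibility 0.6 and GDD 0.4.

What the generator does **not** emulate: real European geography and
coastlines, taxonomic structure beyond genus, inter-model spread of the
glacial ensemble, non-MCAR missingness, abundance information, or
dispersal-limited range cohesion (occupancies are independent draws given
richness and weights). Passing tests therefore demonstrate correctness of
the machinery and recoverability under the stated generating process, not
robustness to every property of real atlas data.

# Numerical choices and degenerate inputs

* Hull volume: support/on-plane tolerance 1e-9 (scaled), hyperplane
  deduplication 1e-7; degenerate inputs return `NA`. Costs grow as
  C(n, d)·n per cell, comfortable for assemblage-sized inputs (n up to a
  few hundred).
* λ search on (−0.999, 0.999); estimates within 1e-4 of the boundary are
  flagged. Pseudo-R² is clipped to [0, 1) and floored at 0 with a warning
  if the optimizer leaves the full model below the null.
* Zero null-model SD yields an undefined SES with a warning; cells whose
  richness cannot support a 4-D hull are `NA` and excluded from pooled
  functional-richness regressions.
* Ties in nearest-neighbour search break towards the lowest cell index;
  duplicate coordinates are an error.
* All generators take explicit integer seeds and are bitwise reproducible;
  derived stage seeds are small fixed offsets of the base seed, recorded
  in the run manifest.

Validation problem sizes (chosen to keep the full suite within a few
minutes while leaving estimator behaviour visible): SAR recovery at
n = 400 over 100 seeds; SES calibration at 200 cells × 500 randomizations;
imputation quality at n = 1000 with 50% MCAR; end-to-end importance
recovery on the 20×20 grid with 6 predictors (729 models) over 20 seeds;
type-I calibration of the corrected correlation over 500 simulated field
pairs.

# Running the pipeline

`run_all(run_config(...))` executes generation → imputation → FD (+SES) →
predictor construction → inference for both FD metrics, writing every
stage as CSV/ESRI-ASCII plus a JSON manifest of configuration and seeds;
reruns of the same configuration are byte-identical. See the README for a
worked example with output.
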