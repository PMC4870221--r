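# paleofd

Quantifying the imprint of late-Quaternary climate change on
continental-scale plant functional diversity.

Across Europe, where a plant assemblage sits relative to Last Glacial
Maximum (LGM, ~21 kyr BP) refugia — and how fast climate has moved since —
still predicts how much trait space the assemblage occupies. `paleofd`
implements the full analysis pipeline behind that kind of question, for
macroecologists and functional biogeographers working with gridded
occurrence atlases:

* **Trait preparation**: log10 transform and z-scoring; gap-filling by a
  genus- and growth-form-constrained chained-equations imputation with
  predictive mean matching, repeated *m* times
  (`log_standardize()`, `mice_impute()`).
* **Functional diversity** per grid cell: functional richness
  *F*<sub>Rich</sub> (convex-hull volume in standardized trait space,
  exact compiled geometry), functional dispersion *F*<sub>Disp</sub> (mean
  distance to the trait centroid), univariate trait range/SD, and
  standardized effect sizes `SES = (obs − mean(null)) / sd(null)` against a
  richness-preserving null model (`fd_pipeline()`).
* **Historical predictors**: ensemble-averaged, change-factor-downscaled
  glacial surfaces; growing degree-days; glacial refugia masks
  (GDD ≥ 800 °C·day, coldest month ≥ −15 °C, summer precipitation
  ≥ 50 mm); climate-change velocity
  `v = |Δclimate|/Δt ÷ |∇climate|` (km·decade⁻¹, Horn 3×3 gradient); and
  accessibility to refugia `A_i = Σ_j 1/d_ij` over refugial cells
  (`climate_velocity()`, `accessibility()`).
* **Spatial regression**: first-nearest-neighbour row-standardized
  weights; maximum-likelihood SAR-error models
  `y = Xβ + u, u = λWu + ε` via the concentrated likelihood with an
  eigenvalue log-determinant; Nagelkerke pseudo-R²;
  Dutilleul-corrected correlations (`fit_sar_error()`, `dutilleul_cor()`).
* **Multimodel inference**: exhaustive enumeration of
  {absent, linear, linear+quadratic} shapes per predictor (3^p SAR-error
  fits), Akaike weights, per-variable relative support
  `W_AIC = Σ w_i` over containing models, conditional model-averaged
  standardized coefficients, and partial residuals `r + b·x`
  (`run_inference()`).
* **Synthetic data**: generators for the whole study system — correlated
  lognormal traits with genus structure, atlas-style missingness,
  occurrence grids along an environmental richness gradient with trait
  filtering, paired present/LGM climate surfaces, and SAR-error responses
  with known parameters — so every stage is testable with no downloads
  (`synthetic_config()`, `generate_traits()`, `generate_response()`).

## Worked example

A miniature end-to-end study on a 10×10 grid of 50 km cells with 120
species:

```r
library(paleofd)

cfg    <- synthetic_config(grid_nrows = 10, grid_ncols = 10,
                           n_species = 120, n_genera = 24,
                           richness_range = c(8L, 30L), seed = 42)
traits <- generate_traits(cfg)
masked <- inject_missingness(traits, cfg$missing_rates, seed = 43)
imp    <- mice_impute(log_standardize(masked), m = 3, seed = 44)
bp     <- build_predictors(cfg, generate_climate_pair(cfg))
occ    <- generate_occurrences(cfg, bp$predictors, traits)
W      <- build_weights(occ$coords)
fd     <- fd_pipeline(occ, imp, n_null = 100, seed = 45,
                      null_metrics = "f_disp")
head(fd$pooled[c("cell", "richness", "f_rich_mean", "f_disp_mean",
                 "ses_f_disp_mean")], 4)
#>              cell richness f_rich_mean f_disp_mean ses_f_disp_mean
#> cell0001 cell0001        8   1.3680490    1.492321      -1.2211926
#> cell0002 cell0002        8   0.9212706    1.494846      -1.3812741
#> cell0003 cell0003        9   2.2576980    1.633154      -0.8693602
#> cell0004 cell0004        9   6.3332241    2.114549       1.6731365
```

Each row is one grid cell, pooled over the 3 imputed trait tables:
`f_rich_mean` is the mean hull volume (standardized trait units⁴),
`f_disp_mean` the mean distance to the trait centroid, and
`ses_f_disp_mean` the dispersion standardized against 100
richness-preserving randomizations (negative = more tightly packed than
expected at that richness).

Exhaustive SAR-error multimodel inference for functional richness over the
six predictors (3⁶ = 729 models per imputation replicate):

```r
inf <- run_inference(bp$predictors,
                     lapply(fd$replicates, `[[`, "f_rich"), W,
                     log10_predictors = c("temp_velocity", "prec_velocity",
                                          "annual_prec"))
inf
#> inference_result: 3 replicate(s), 729 models over 6 predictors
#>
#> Relative support (W_AIC, pooled):
#>      predictor  mean    lo    hi
#>  accessibility 1.000 1.000 1.000
#>  temp_velocity 0.532 0.395 0.686
#>  prec_velocity 0.585 0.495 0.695
#>            gdd 0.695 0.480 0.926
#>          tcold 0.583 0.456 0.784
#>    annual_prec 0.569 0.453 0.739

subset(inf$coefficients, predictor == "accessibility")
#>       predictor term      mean         lo        hi
#> 1 accessibility    b 0.9203938 0.89624169 0.9402320
#> 2 accessibility   b2 0.1060144 0.06098912 0.1564089
```

Accessibility to glacial refugia drives richness in this synthetic system
by construction, and the inference recovers it: relative support
(`W_AIC`) of 1.00 in every imputed replicate and a strongly positive
model-averaged standardized coefficient (0.92, 95% interval across
replicates 0.90–0.94), while the five bystander predictors sit near the
uninformative baseline. `run_all(run_config(...))` wraps this whole
sequence, including partial-residual tables for the historical predictors,
and writes every stage plus a seed manifest to an output directory.

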