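# beescape

Satellite-image texture metrics as predictors of wild-bee biodiversity.

Heterogeneous landscapes offer more ecological niches and tend to host
more species. `beescape` implements, as reusable R functions, an analysis
chain that asks how much of the local biodiversity of wild bees —
abundance, Shannon diversity, rarefied species richness — can be explained
by spatial heterogeneity measured from above: image texture of an NDVI
raster and terrain roughness of a DEM, summarized in distance classes
around flight traps. It is written for ecologists and remote-sensing
researchers who want each stage of such an analysis as a tested,
scriptable building block, together with a synthetic-data generator so the
entire chain can be exercised and calibrated without any field data.

## What it computes

* **Texture layers** — NDVI from red/NIR bands; first-order moving-window
  statistics of the quantized index (mean, entropy −Σ P(i) ln P(i),
  evenness, variance); grey-level co-occurrence (GLCM) statistics
  averaged over four angles (contrast Σ P(i,j)(i−j)², dissimilarity,
  entropy, homogeneity Σ P(i,j)/(1+(i−j)²)); terrain roughness
  √Σ(x_ij − x₀₀)² over the 8-neighbourhood, smoothed in a 9×9 window.
  Kernels are in C++ with an independent R enumeration oracle.
* **Zonal predictors** — ring buffers (100–1000 m) around traps;
  mean / SD / CV of each layer over the cells inside each ring; a tidy
  predictor table, one row per trap.
* **Biodiversity responses** — per trap × year × season for bumble bees,
  solitary bees and all wild bees (honeybees excluded): normalized bee
  count, Shannon diversity, and species richness rarefied (hypergeometric)
  or extrapolated (Chao1) to three times the minimum community abundance.
* **Screening** — distance-class pruning at |r| > 0.7, between-variable
  pruning by a biological-importance ranking, and iterative VIF filtering
  at √VIF > 2, all with logged reasons.
* **Multimodel inference** — all-subsets OLS with fixed control factors
  (site, year, season), AIC ranking, ΔAIC ≤ 2 top-set Akaike-weighted
  model averaging (full/zero-substitution, with unconditional SDs and
  relative importance), likelihood-ratio p-values, and global-versus-null
  R² comparison.
* **Spatial diagnostics** — distance-binned Moran-type correlograms of
  model residuals with permutation significance and spline smoothing.
* **Synthetic data** — Voronoi field mosaics with tunable field size,
  Gaussian-random-field DEMs, gridded jittered traps, and negative-
  binomial bee communities whose log-expected counts respond to the local
  entropy and roughness predictors.

## Worked example

Simulate a study site, build the responses, screen the predictors and fit
the averaged model for log bee count of all wild bees:

```r
library(beescape)
library(dplyr)

sim <- simulate_study(seed = 2026)          # landscape, traps, predictors, records
bio <- add_bc_log(build_biodiversity(sim$records))

vdat <- inner_join(filter(bio, group == "nohb")[c("trap_id", "year", "season")],
                   sim$predictors, by = "trap_id")
scr <- screen_predictors(sim$predictors, vif_data = vdat)
scr$report$kept_columns
#>  [1] "NDVI_cv_100"    "NDVI_cv_200"    "NDVI_cv_500"    "NDVI_cv_800"
#>  [5] "ent1_mean_100"  "ent1_mean_500"  "ent1_mean_1000" "rough_mean_100"
#>  [9] "rough_mean_500" "rough_mean_1000"

pred   <- scale_predictors(scr$table)
tests  <- head(predictor_columns(pred), 5)
joined <- inner_join(filter(bio, group == "nohb"), pred, by = "trap_id")
fit <- fit_texture_model(joined, "BC_log", tests, usable_controls(joined))
fit
#> <bee_texture_model> response BC_log, 5 models averaged
#> # A tibble: 5 × 5
#>   term           estimate     sd importance p.value
#>   <chr>             <dbl>  <dbl>      <dbl>   <dbl>
#> 1 NDVI_cv_100   -0.000574 0.0230      0.145  0.904
#> 2 NDVI_cv_200   -0.00107  0.0193      0.146  0.796
#> 3 NDVI_cv_500    0.00266  0.0206      0.154  0.594
#> 4 NDVI_cv_800    0.00376  0.0220      0.162  0.676
#> 5 ent1_mean_100  0.144    0.0516      1      0.0204
#> R2 global 0.374, null 0.314, delta 0.060
```

Reading the output: estimates are model-averaged effects per SD of each
predictor on log bee count. The generator planted a positive effect of
local first-order entropy (0.1 per SD); the fitted 0.144 ± 0.052 with
importance 1 and p = 0.02 recovers it, while the undriven NDVI-CV columns
shrink towards zero with low importance. The texture predictors add
ΔR² = 0.06 over the site/season/year controls. `tidy(fit)`, `glance(fit)`
and `autoplot(fit)` give the tibble, the R² block and a forest plot;
`residual_correlogram()` then checks the residuals for spatial structure.

The staged pipeline wraps all of this with artifacts and manifests:

```r
cfg <- run_config(outdir = "run1", seed = 7)
run_pipeline(cfg)   # simulate → textures → buffers → diversity → screen → fit → diag
```

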