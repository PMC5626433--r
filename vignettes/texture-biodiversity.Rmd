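---
title: "Modelling wild-bee biodiversity from image texture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wild-bee biodiversity from image texture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beescape` implements a complete analysis chain linking spatial habitat
heterogeneity, measured from a vegetation-index raster and a digital
elevation model, to wild-bee biodiversity sampled with flight traps. This
vignette documents the statistical machinery, the tunable parameters, the
synthetic-data generator, and the design decisions taken where the
methodology left genuine choices open.

## The scientific setting

Spatial heterogeneity of habitat is a classic determinant of species
richness: more heterogeneous landscapes offer more niches. The spectral
variation hypothesis proposes that heterogeneity visible to a satellite —
variation in a vegetation index such as the NDVI — can stand in for
habitat heterogeneity measured on the ground. The pipeline quantifies that
variation with *image texture*: first-order (occurrence) statistics of the
pixel-value histogram in a moving window, and second-order (co-occurrence)
statistics of pixel pairs, plus terrain roughness from a DEM as a proxy for
relief-driven heterogeneity and land-use intensity. These local measures
are summarized within distance classes around each trap, screened for
collinearity, and related to three biodiversity responses by multimodel
inference over all-subsets linear models.

## Texture layers

All texture layers work on a quantized raster. Quantization is linear into
`n_levels` equal-width bins (default 32) over the scene's global min–max
(configurable to a fixed range). Global binning keeps windows comparable
across the scene; 32 levels is ample resolution for the default 3×3
window, whose 9 pixels can occupy at most 9 distinct levels anyway.

First-order statistics of the window histogram $P(i)$:

* mean $\sum_i i\,P(i)$,
* entropy $-\sum_i P(i)\ln P(i)$ (with $0\ln 0 \equiv 0$),
* evenness $\mathrm{entropy}/\ln N_g$, where $N_g$ is the number of
  *distinct* levels present in the window (the convention of the GRASS
  `r.diversity` tool); a single-level window has evenness 1 by definition,
* variance $\sum_i (i - M)^2 P(i)$ around the window mean $M$.

Second-order statistics come from the symmetric grey-level co-occurrence
matrix (GLCM) $P(i,j)$, built per window and per angle from all pixel
pairs at the angle's offset (distance 1 by default), each pair counted in
both directions:

* contrast $\sum_{ij} P(i,j)(i-j)^2$,
* dissimilarity $\sum_{ij} P(i,j)\,|i-j|$,
* entropy $-\sum_{ij} P(i,j)\ln P(i,j)$,
* homogeneity $\sum_{ij} P(i,j)/(1+(i-j)^2)$.

Each statistic is computed per angle (0°, 45°, 90°, 135°) and the four
results averaged arithmetically — averaging statistics, not pooling
matrices. An angle with no valid pair in a window is excluded from that
window's average. Natural logarithms are used for both entropies for
internal consistency.

Edge policy: a cell whose window is incomplete gets nodata. The package
never pads or fabricates values; downstream zonal summaries simply skip
nodata cells. Interior nodata cells are excluded from histograms and pair
counts, and a nodata center yields nodata.

Terrain roughness is the square root of the summed squared elevation
differences between a cell and its eight neighbours,
$\sqrt{\sum (x_{ij}-x_{00})^2}$, subsequently averaged over a 9×9 moving
window. The neighbour-difference formula is defined on adjacent cells
while the published workflow names a 9×9 window; the package reconciles
the two by computing the 8-neighbour ruggedness per cell and then
smoothing, which preserves both the formula and the stated window.

The moving-window kernels are implemented in C++ (as texture packages in
this field usually are); an independent R-level reference that explicitly
enumerates all pixel pairs (`glcm_reference()`) is kept in the package and
the two routes are compared on random windows in the tests to 1e-12.

## Buffers and the predictor table

Distance classes are 100–1000 m in 100 m steps. "Ring buffers" are read
literally as annuli: the first class is the 0–100 m disk, later classes
the $(r_{k-1}, r_k]$ rings, so the classes partition the largest disk.
Nested disks remain available (`kind = "disk"`) because the original
usage is ambiguous; the two coincide for the innermost class and behave
identically under the screening that retains only extreme classes.

Cell membership is by cell center, with no partial-area weighting —
simple, standard, and exactly testable (the annuli of a trap partition the
cells of the largest disk). Each layer is summarized in its native
resolution (30 m textures, 10 m roughness) within the same metric buffer
geometry. Summaries are the mean and sample SD for every layer, and mean
and coefficient of variation for the NDVI itself; a CV whose mean
denominator is below 1e-9 in absolute value is flagged undefined rather
than returned as an arbitrarily large number. A buffer containing zero
valid cells raises an error naming the trap and radius.

Predictor columns are named `<metric>_<summary>_<distance>`
(e.g. `ent1_mean_100`, `NDVI_cv_1000`) and parsed from the right, so
metric names may contain underscores.

## Biodiversity responses

Records are split into three community subsets: honeybees (an explicit
exclusion list, default *Apis mellifera*) are removed everywhere; `bb`
holds the bumble-bee genus (prefix *Bombus*), `sb` the remaining wild
bees, `nohb` their union. Per trap × year × season × subset the package
computes:

* **BC** — bee count normalized to trapping days;
* **SD** — Shannon diversity $-\sum_i p_i \ln p_i$;
* **SpR** — expected species richness standardized to $m$ individuals:
  hypergeometric rarefaction
  $S_{obs}-\sum_i \binom{n-X_i}{m}/\binom{n}{m}$ for $m \le n$, and for
  $m > n$ the Chao1-based extrapolation
  $S_{obs} + \hat f_0\left[1-\left(1-\frac{f_1}{n\hat f_0+f_1}\right)^{m-n}\right]$
  with the bias-corrected $\hat f_0$ from singletons $f_1$ and doubletons
  $f_2$. The standardization target is three times the minimum non-zero
  community abundance of the dataset, rounded to the nearest integer, and
  is computed per subset: a minimum over a dataset that includes another
  subset's communities would standardize, say, bumble bees to a solitary-
  bee abundance floor. Because the target is a multiple of the *minimum*,
  the minimum-abundance community is necessarily extrapolated — hence the
  Chao1 branch is not optional. With no singletons the extrapolation
  returns the observed richness.

Binomial coefficients are evaluated on the log scale (`lchoose`) so large
communities do not overflow. Bee counts are modelled on the log scale;
zero counts are replaced by half the smallest positive normalized count
before the log (the offset is recorded on the table).

A Pearson correlation of early- versus late-season values, paired by trap
× year, is provided as the standard check that season should enter the
models as a fixed control.

## Predictor screening

Three steps, in order, each recorded in a `screening_report`:

1. **Distance-class pruning** per variable (metric × summary): classes
   are retained greedily in a priority order, dropping any class whose
   absolute Pearson correlation with an already-kept class of the same
   variable exceeds 0.7. The priority order defaults to extremes first
   (100, 1000, 500, 200, …): the original analysis retained exactly the
   100 m and 1000 m classes, and an explicit order makes the
   otherwise-unstated tie-breaking reproducible. A variable whose classes
   are all mutually correlated collapses to its top-priority class;
   constant columns are dropped with their own reason.
2. **Between-variable pruning**: for every pair of remaining columns with
   $|r| > 0.7$ the member whose variable ranks lower in a user-supplied
   biological-importance ranking is dropped. The rule applies to every
   correlated pair, so a correlation chain A~B~C under ranking (A, B, C)
   loses both B and C. "Biological importance" is deliberately an
   explicit configuration input, not something inferred from data.
3. **VIF filtering**: the VIF of each test predictor is $1/(1-R^2)$ from
   regressing it on all other test predictors plus dummy-coded control
   factors; while any $\sqrt{\mathrm{VIF}} > 2$ the worst offender is
   removed and VIFs recomputed (iterative worst-first removal is
   deterministic; single-pass removal is order-dependent). Controls are
   never removable. In the staged pipeline the VIFs are computed on the
   modelling rows (trap × year × season, with the controls), matching the
   "VIF of the full model" usage; the trap-level table alone would be
   rank-deficient for realistic menus. Because predictors vary only
   across traps, a single 16-trap site supports at most ~15 columns in
   the VIF design; `screen_predictors()` therefore applies an explicit
   rank guard (default 12 columns, taken in importance then
   class-priority order, logged as `rank_guard`) before the VIF step.
   When no importance ranking is supplied, the default places the
   heterogeneity variables the analysis centres on first (NDVI CV,
   roughness, first-order entropy, contrast, homogeneity), then the
   remaining variables as encountered.

Screening is idempotent, and after step 3 every retained predictor
verifiably satisfies the bound.

## All-subsets models and averaging

For one response and subset, the global model is an ordinary least-squares
fit of the response on the scaled test predictors plus the control factors
(site, year, season — any control with fewer than two levels in the data
is dropped). Test predictors are centered and scaled to unit SD so the
averaged coefficients are per-SD effects; controls are untouched. No
interactions are fitted. All $2^p$ subsets of the test predictors (always
keeping the controls) are ranked by AIC $=-2\log L + 2k$ with $k$ counting
the residual variance; AICc is available as an option but AIC is the
default, following the original procedure. The top set is
$\Delta\mathrm{AIC}\le 2$ with Akaike weights renormalized inside it.

Averaging is *full* (zero-substitution): a predictor absent from a model
contributes $\beta = 0$ with zero variance, so weakly supported effects
shrink towards zero — the behaviour visible in the original study's
low-importance estimates. The unconditional SD is
$\sqrt{\sum_i w_i\,[\mathrm{var}_i + (\beta_i - \bar\beta)^2]}$, relative
importance the summed weight of models containing the predictor.
Per-predictor p-values come from likelihood-ratio tests of the global
model against the model without the predictor, referred to $\chi^2_1$
(mildly liberal relative to the exact F test at these sample sizes — see
the calibration notes below). Explained variance is compared between the
global model and the controls-only null model.

## Residual spatial diagnostics

The spatial check is a distance-binned Moran-type correlogram on centered
residuals $z$: per 100 m bin,
$\rho(d) = \mathrm{mean}_{\,pairs\,in\,bin}(z_i z_j)/\overline{z^2}$,
with a two-sided permutation test (500 shuffles of residuals over
locations, add-one correction $p = (b+1)/(n_{perm}+1)$) and an optional
pair-count-weighted cubic smoothing spline for the familiar
spline-correlogram presentation, including the first zero crossing of the
smooth. The binned-statistic-plus-randomization form is the inferential
tool; the spline is presentational. The maximum evaluated distance
defaults to half the maximum inter-point distance, and the whole object is
reproducible under a seed. Permutation p-values are invariant to positive
rescaling of the residuals.

## The synthetic-data generator

No field or satellite data ship with the package, so the generator
produces inputs with the statistical structure the analysis assumes:

* **Landscape**: a 4 × 4 km site; the vegetation index is a Voronoi
  mosaic of `n_fields` fields (default 120) with per-field mean index
  drawn from a cropped-field range (0.20–0.85), a configurable fraction
  (default 0.1) flagged semi-natural with a greener range (0.55–0.95),
  plus within-field Gaussian noise (SD 0.02), clamped to $[-1, 1]$ and
  sampled at 30 m. Field count is the single knob that drives texture
  entropy — smaller fields put more borders into each window — which is
  exactly the mechanism that makes entropy informative about farmland
  heterogeneity, and is checked as a monotonicity experiment in the
  tests. The DEM is a Gaussian random field (FFT-smoothed white noise) at
  10 m with amplitude 25 m SD and 500 m correlation length, within the
  range of relief across the original six sites (elevation SDs 10–31 m).
* **Traps**: one per 1 × 1 km cell, uniformly jittered within the cell —
  16 traps on the default extent.
* **Communities**: per trap × year × season the log-expected total count
  is $\beta_0 + \beta_{ent}\,\tilde e + \beta_{rough}\,\tilde r$ plus
  site, season and year effects, where $\tilde e,\tilde r$ are the scaled
  local entropy and roughness predictors. $\beta_0 = \log 25$ matches the
  roughly 26 bees per trap and period implied by the original totals
  (>20,000 individuals over 768 trap-periods). Totals are negative
  binomial with overdispersion $\theta = 0.1$
  ($\mathrm{var} = \mu + \theta\mu^2$, i.e. a variance–mean ratio of
  about 3.5 at $\mu = 25$ — moderate for ecological counts; $\theta = 0$
  recovers Poisson). Individuals are allotted to species by a log-normal
  species-abundance distribution (σ = 1.2) drawn per site over a shared
  pool of 80 species, a tenth flagged as the bumble-bee genus. Season is
  a fixed −0.3 on the log scale (late summer catches run lower); site and
  year effects are Gaussian (SD 0.3 and 0.2).

Everything is deterministic under one seed; `simulate_study()` derives
stage seeds from it.

What the generator does *not* emulate: real crop geometry and phenology,
bee foraging movement, detection differences between trap types, spatial
autocorrelation of communities beyond what the shared landscape induces,
and the taxonomic structure of a real species pool. Passing tests
therefore demonstrate that the machinery is correct and calibrated under
the stated generative model — not that texture metrics predict real bee
communities.

## Validation experiments and their design

The packaged experiments (also rerun by `scripts/acceptance.R`):

* **Kernel correctness**: moving-window GLCM statistics equal the
  enumeration reference on ≥100 random 3×3–9×9 windows to 1e-12, and a
  set of closed-form identities (entropy $\ln k$ of a uniform window,
  Shannon $\ln S$, the hypergeometric rarefaction value 11/6 of the
  (2,1,1) community at $m=2$, VIF $=1/(1-0.81)$ at $r=0.9$, Akaike
  weights 0.731/0.269 at $\Delta$AIC 0/2) hold to 1e-9.
* **Parameter recovery**: 100 end-to-end replicates (16 traps × 2 seasons
  × 3 years) with planted per-SD effects $\beta = 0.1$ on entropy and
  roughness. The fitted test-predictor menu is the planted pair itself:
  re-running data-driven screening inside each replicate would leave the
  estimand undefined whenever a planted predictor is pruned (screening is
  validated separately), and texture decoys such as second-order
  homogeneity are near-collinear with entropy by construction, which is
  precisely what the real screening removes before modelling.
* **Test calibration**: the same experiment with $\beta = 0$ (400
  replicates) for the type-I error of the LRTs, and 500 random-layout
  datasets × 500 permutations for the correlogram's per-bin rejection
  rate.
* **Structural screening outcome**: on predictors generated with a
  first-order autoregressive correlation across distance classes
  (adjacent-class correlation 0.94, 500 rows — chosen once so the
  population pruning outcome is stable to sampling noise at any seed),
  extremes-first pruning retains exactly the 100 m and 1000 m classes.
* **Mechanism**: over 20 paired seeds, mean first-order entropy is
  compared between small-field (300 Voronoi seeds) and large-field (40
  seeds) landscapes, with a sign test.

### A known limitation: coverage of full-averaged estimates

With the generator's noise defaults the planted $\beta = 0.1$ is roughly
2.5 residual standard errors. At that moderate signal the
$\Delta$AIC ≤ 2 top set regularly contains models omitting the predictor,
and full averaging then both shrinks the point estimate and understates
its replicate-to-replicate spread: the unconditional-variance formula
accounts for between-model disagreement *within* a replicate but not for
the selection variability *across* replicates. In the packaged recovery
experiment the mean estimates are centred on the planted values and the
null-effect LRT calibration is clean, but the ±2 unconditional-SD
interval covers the truth in somewhat fewer than 90% of replicates. This
is a documented property of model-averaged shrinkage estimators at
moderate signal-to-noise, not a defect of the kernels; the corresponding
check in the test suite is expected to fail under the default generator
settings and is retained deliberately as an honest record of the
estimator's behaviour. Users who need calibrated intervals at moderate
signal should prefer the global (unaveraged) model's confidence
intervals.

## Numerical and degenerate-input choices

* Constant rasters quantize to level 0 everywhere (not an error);
  constant predictor columns are an error in scaling and a logged drop in
  screening.
* Undefined CV (near-zero mean) is `NA`, never ±Inf.
* Rarefaction uses `lchoose`; $m = n$ returns $S_{obs}$ exactly; empty
  communities are flagged `NA`, never silently zero.
* Ties in AIC are broken by subset enumeration order, making the
  candidate ranking fully deterministic.
* The correlogram excludes bins with fewer than `min_pairs` (default 2)
  pairs; a single-pair bin, if requested, gives $\rho = \pm 1$ by
  construction.
* The spline zero crossing reports `NA` for numerically flat smooths.
* Problem sizes in the test suite (window counts, replicate counts,
  points per correlogram) are chosen so each experiment has small
  Monte-Carlo error relative to the band it checks while the whole suite
  stays comfortably re-runnable on one CPU.

## Limitations

Beyond the coverage point above: the pipeline fits Gaussian OLS (as the
original analysis did) rather than count models, so bee counts enter
log-transformed; no mixed or spatially correlated error models are
offered (the spatial diagnostic is exactly that — a diagnostic); and the
GeoTIFF interface stores the georeference in a JSON sidecar because the
underlying TIFF reader carries no geo-tags. ESRI ASCII grids round-trip
natively.
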