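---
title: "Regression kriging of grassland carbon stocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression kriging of grassland carbon stocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steppeRK)
```

## The model

steppeRK implements two-step regression kriging (RK) for scaling
plot-measured grassland carbon density (gC/m²) to a regional map using
reflectance covariates:

$$\hat z_{RK}(s_0) = \sum_{k=0}^{p} \hat\beta_k\, q_k(s_0)
  \;+\; \sum_{i=1}^{n} \lambda_i\, e(s_i).$$

Step one regresses carbon on the covariates $q_k$ by ordinary least
squares; step two models the spatial autocorrelation of the OLS residuals
$e(s_i)$ with a semivariogram and interpolates them by ordinary kriging
(OK). The prediction is the sum of the two terms, and the linear
regression (LR) baseline is simply the first term alone
(`predict(fit, type = "trend")`).

Assumptions, stated plainly:

* the trend is linear in the covariates with an intercept, so the
  residuals sum to zero and the mean of the residual field is zero;
* the residual field is second-order stationary and isotropic — a single
  omnidirectional variogram $\gamma(h)$ describes its structure;
* carbon is modelled directly in gC/m² (no transformation), appropriate
  when the plot data are approximately normal;
* the trend is deliberately plain OLS rather than GLS: the procedure is
  sequential by construction, and the kriging step consumes whatever the
  OLS trend leaves behind.

The biomass-to-carbon step uses the grassland conversion coefficient 0.45
(forests conventionally use 0.5): `carbon = 0.45 * agb`.

### Variograms

Three families are supported, in the parameterisation with nugget $c_0$,
partial sill $c_1$ and *distance parameter* $a$:

* exponential: $\gamma(h) = c_0 + c_1(1 - e^{-h/a})$, effective range $3a$;
* Gaussian: $\gamma(h) = c_0 + c_1(1 - e^{-(h/a)^2})$, effective range
  $\sqrt 3\,a$;
* spherical: $\gamma(h) = c_0 + c_1(1.5\,h/a - 0.5\,(h/a)^3)$ for
  $h \le a$, else $c_0 + c_1$.

Conventions differ between software packages on whether "range" means $a$
or the effective range; pinning $a$ (and reporting the effective range
alongside, `effective_range()`) makes fitted models reproducible.
$\gamma(0) = 0$ always; the nugget appears only for $h > 0$.

The empirical semivariogram is the classical Matheron method-of-moments
estimator on equal-width distance bins over $(0, \text{max\_lag}]$. The
defaults — 15 bins, max lag equal to half the maximum pairwise distance —
are the common heuristics and are configurable. Robust (Cressie–Hawkins)
estimation, anisotropy and REML fitting are out of scope.

Fitting minimises the weighted SSE with Cressie weights
$w_j = N_j / \gamma(h_j)^2$ (pair count over the squared *model*
semivariance, guarded below by $10^{-10}$ so near-zero model values cannot
produce infinite weights), using L-BFGS-B with bounds $c_0, c_1 \ge 0$,
$a \in (0, 3\,\text{max\_lag}]$ and four starts: $c_0 = \min\hat\gamma$,
$c_1 = \max\hat\gamma - \min\hat\gamma$, $a \in \text{max\_lag}\cdot\{1/10,
1/3, 1\}$, plus a nugget-leaning start for flat empirical variograms. The
best of the converged starts wins. When all three families are fitted
(`fit_all_variograms()`), equal weighted SSEs break ties in the order
exponential < Gaussian < spherical; final family selection is by LOOCV
(`model_selection()`), not by SSE.

### The kriging solver

`solve_ok()` solves the semivariance-form OK system
$[\Gamma, \mathbf 1; \mathbf 1^\top, 0]\,[\lambda;\mu] = [\gamma_0; 1]$
with a zero diagonal in $\Gamma$ (the $\gamma(0)=0$ convention). Under a
nugget this makes kriging non-exact at the samples, as theory dictates.
Design choices worth knowing:

* **global neighbourhood** — all samples enter every prediction; with
  $n \le$ a few hundred plots this is both exact and fast, and the batch
  form (`ok_predict_points()`) factorizes the $(n+1)\times(n+1)$ matrix
  once and solves all targets in a single LAPACK call;
* **duplicate coordinates are a hard error** naming the offending pair —
  silent jittering would change results irreproducibly;
* the covariance-form solution ($C(h) = c_0 + c_1 - \gamma(h)$) is
  mathematically identical for finite-sill models and is used as an
  independent oracle in the tests, never as the implementation.

Two limiting behaviours anchor the test suite: with a pure-nugget
variogram the weights collapse to $1/n$ and RK degenerates to LR exactly
(the residuals average zero); with zero nugget the predictor interpolates
the observations exactly.

### Model assessment

LOOCV refits the trend on $n-1$ plots per fold; the residual variogram is
fitted once on the full sample and held fixed across folds (the
`variogram_policy = "fixed"` default). Rationale: refitting a 15-bin
variogram on $n-1$ of ~50 points per fold is unstable, and holding it
fixed matches the standard cross-validation behaviour of geostatistical
tooling; `"refit"` is available as a config switch. Metrics are
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, MAE and RMSE, with MAE reported in
gC/m² (the units its comparison tables carry). Strata are validated
separately and pooled by concatenating the held-out pairs and recomputing
the metrics on the pooled vectors — not by averaging per-stratum metrics.
Model selection ranks by $R^2$ descending with ties broken by lower RMSE,
then lower MAE, then input order.

Pearson screening (`pearson_screen()`) reports $r$ per covariate for all
plots and per stratum, with the two-sided $t$-test $p$-value and a
significance flag at $p < 0.01$; no multiple-testing correction is
applied, matching the descriptive role the screen plays.

## Spectral covariates

`compute_index()` computes NDVI, WDRVI, CI, EVI and SR from 7-band
top-of-canopy reflectance, with the standard OLI band mapping fixed as
B2 = blue, B3 = green, B4 = red, B5 = NIR. Constants: WDRVI weighting
$\alpha = 0.1$; EVI $L = 1$, $C_1 = 6$, $C_2 = 7.5$. Raw WDRVI values over
grassland are small and mostly negative, so the conventional offset
$0.9/1.1$ is added and the index is carried in shifted form only — a
single canonical covariate avoids ambiguity, and Pearson screening is
shift-invariant, so nothing downstream changes. Division-by-zero pixels
become nodata rather than ±Inf (regression must see finite covariates),
nodata propagates, and reflectance outside $[0, 1.5]$ is flagged with a
warning but never silently clamped. Plot extraction is nearest-pixel, not
bilinear: a plot is defined as one homogeneous 30 m pixel.

Without a GeoTIFF reader among the package's dependencies, rasters live in
a minimal in-memory `grid_stack` container (named band matrices + origin,
pixel size, CRS label, nodata) and are serialized as plain-text ESRI ASCII
grids with a `stack.json` sidecar pinning band order. The format is
readable by every mainstream GIS.

## Stratified mapping and accounting

The four steppe classes map to two model strata — lowland meadow and
temperate meadow to *meadow*; temperate typical and sandy to *typical* —
and each stratum is predicted by its own RK model at the masked pixel
centres, then mosaicked (overlapping valid pixels are an error).
Negative predictions are clamped to zero *only* at the mapping stage,
with a recorded count; cross-validation never clamps, so metrics are
untouched. The accounting unit chain is pinned once: gC/m² × m² → g,
1 Mg = 10⁶ g, 1 hm² = 10⁴ m², outputs in 10⁴ hm² and 10⁴ Mg C. Two
identities close the books and are asserted in the tests: per-class totals
sum exactly to the all-class total, and the all-class mean density equals
total/area after unit conversion. `carbon_accounting()` applies the same
chain to a tabulated per-class area/mean summary, which is how the
package reproduces a published regional table from its printed inputs.

## The synthetic study generator

Field plots from regional carbon surveys are rarely published, so the
generator (`synthetic_config()` + `simulate_plots()`) creates studies with
*known* structure for parameter-recovery testing:

* 84 plots — 55 typical-steppe in the western half, 29 meadow-steppe in
  the eastern half of a 10 km × 10 km projected domain (uniform within
  each half; the east/west split echoes the west-to-east productivity
  gradient of the steppe system it emulates);
* one smooth covariate surface per configured covariate (superposed
  random cosines with correlation scale 2000 m plus an eastward drift,
  rescaled to an NDVI-like [0.1, 0.9]);
* carbon = 11 + 60 × covariate + a Gaussian-random-field residual with an
  exponential variogram ($c_0 = 20$, $c_1 = 80$, $a = 2500$ m — nugget
  fraction 0.2, range = extent/4). These values were calibrated once so
  the simulated carbon distribution sits near the published field
  statistics (mean ≈ 38.8, sd ≈ 16.2 gC/m²) and the covariate–carbon
  Pearson correlation centres in the 0.6–0.85 band typical of
  reflectance covariates over grassland;
* negative carbon is clamped to zero and counted — carbon is nonnegative
  by definition;
* point-level fields are drawn by Cholesky factorization of the
  covariance $C(h) = c_0 + c_1 - \gamma(h)$ (with a documented fallback of
  at most $10^{-8}\cdot$sill diagonal jitter if the factorization fails);
  full-raster surfaces use the random-cosine approximation, which is cheap
  where a Cholesky draw is not.

`make_fixture_stack()` builds a 7-band 30 m reflectance stack by
*inverting* the index formulas from designed NDVI and CI surfaces (red
fixed at 0.1, NIR solved from NDVI, green from CI), so `compute_index()`
recovers the designed surfaces to machine precision — the stack is
correct by construction, not by measurement. The designed CI carries an
independent perturbation so NDVI and CI are correlated but not collinear.

What the generator does **not** emulate: Landsat radiometry, atmospheric
effects, cloud/shadow masks, mixed pixels, plot-location error, or the
actual spatial pattern of any real steppe. Passing tests therefore
demonstrate that the estimation chain recovers known structure under its
own assumptions — linear trend, stationary isotropic residuals — not that
those assumptions hold for any particular satellite product or region.
The plot layout itself is a modelling choice, not a reconstruction: the
emulated survey's real layout is unpublished.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than silently: zero-area
extents, all-zero pairwise distances, rank-deficient trend designs (error
names the collinear columns), constant observations in $R^2$ (explicit
error; MAE/RMSE still available on request), empty zonal classes, and
all-zero totals in proportions (defined as 0 with a warning). Histogram
fractions always sum to one per class because out-of-range densities are
counted into the boundary bins.

The test and reproduction problem sizes are chosen to exercise the
estimators where their behaviour is informative while keeping every run
interactive: variogram recovery uses 300-point fields over 20 seeds
(median recovered range and sill against an exponential truth with
$c_0 = 0.1\sigma^2$, $c_1 = 0.9\sigma^2$, $a$ = extent/5); the RK-vs-LR
comparison runs 25 seeded 84-plot studies through stratified LOOCV; field
draws are validated on a 100-point transect averaged over 60 replicates.

## Known limitations

* Global-neighbourhood OK scales as $O(n^3)$ in the plot count; hundreds
  of plots are fine, tens of thousands are not (a local-neighbourhood
  option is future work).
* Kriging-variance surfaces for the final carbon product are not
  produced, and there is no uncertainty propagation through the
  accounting.
* Fitted empirical models are specific to their region and season; the
  package makes no claim of transferability, which is a property of all
  empirical carbon models, not of the implementation.
* The variogram bin count, max lag and fit criterion are declared
  defaults, not values inferred from any particular study; sensitivity to
  them should be checked per application.
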