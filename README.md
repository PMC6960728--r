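# steppeRK

Regression kriging of grassland above-ground carbon stocks from multiband
surface reflectance.

## The problem

Plot harvests give accurate above-ground biomass — and, via the grassland
conversion coefficient 0.45, carbon density in gC/m² — but only at a handful
of 30 m plots. Scaling those measurements to a regional carbon map needs a
spatial predictor built from wall-to-wall covariates (reflectance bands and
vegetation indices). A plain linear regression (LR) on such covariates
ignores the spatial autocorrelation left in its residuals; regression
kriging (RK) recovers it:

```
ẑ_RK(s₀) = Σₖ β̂ₖ qₖ(s₀)  +  Σᵢ λᵢ e(sᵢ)
```

an ordinary-least-squares trend on the covariates qₖ plus an
ordinary-kriging (OK) interpolation of the trend residuals e(sᵢ), with
kriging weights λᵢ (Σλᵢ = 1) determined by a semivariogram model
(exponential, Gaussian or spherical; nugget c₀, partial sill c₁, range a)
fitted to the empirical Matheron semivariogram of the residuals. Competing
models are compared by leave-one-out cross-validation (LOOCV) using R²,
MAE and RMSE, the two steppe strata (typical and meadow) are modelled
separately and mosaicked, and the final map is summarised by zonal carbon
accounting (area, mean density, total stock, class proportions).

The package is aimed at spatial ecologists estimating grassland carbon (or
any plot-to-region scaling of a density variable) who want the whole chain
— vegetation indices, variogram modelling, the OK solver, LOOCV model
comparison, stratified mapping and accounting — as tested, scriptable R
functions. A seeded synthetic-field generator with known trend and
residual-variogram structure makes every stage testable by parameter
recovery.

## What is in the box

- `compute_index()`, `agb_to_carbon()` — NDVI, WDRVI (stored with the
  conventional 0.9/1.1 offset), CI, EVI, SR from 7-band top-of-canopy
  reflectance; biomass→carbon with coefficient 0.45.
- `empirical_variogram()`, `fit_variogram()`, `fit_all_variograms()` —
  Matheron estimator and bounded weighted-least-squares fits (Cressie
  weights, multi-start) of the three classical families.
- `solve_ok()`, `ok_predict_points()` — the semivariance-form OK system
  with Lagrange multiplier; batch targets share one factorization.
- `rk()` — the central fitting function (formula + data interface)
  returning an S3 `"rk"` object with `print`, `summary`, `coef`,
  `residuals`, `predict` (`type = "rk"` or `"trend"` for the LR baseline),
  `plot` and JSON serialization; `variable_importance()` ranks covariates
  by |standardized coefficient|.
- `pearson_screen()`, `loocv()`, `combine_strata_cv()`,
  `model_selection()`, `rk_metrics()` — covariate screening and LOOCV
  model comparison.
- `predict_stratum_map()`, `mosaic()`, `zonal_summary()`,
  `carbon_accounting()`, `histogram_by_class()` — stratified mapping and
  carbon accounting with a pinned unit chain (gC/m² × m² → g; 1 Mg = 10⁶ g;
  1 hm² = 10⁴ m²).
- `synthetic_config()`, `simulate_plots()`, `simulate_gaussian_field()`,
  `make_fixture_stack()` — the synthetic study generator.
- `rk_run()` — an end-to-end driver (simulate → indices → screen → fit →
  cv → predict → summarize) with a JSON config; a thin command-line
  wrapper lives at `inst/scripts/rk-pipeline.R`. Rasters are read and
  written as plain-text ESRI ASCII grids with a JSON sidecar.

## Worked example

```r
library(steppeRK)

cfg   <- synthetic_config(seed = 7)      # 84 plots: 55 typical + 29 meadow
plots <- simulate_plots(cfg)

fit <- rk(carbon_gc_m2 ~ ndvi, plots, family = "all")
summary(fit)
#> Regression-kriging model
#>   n = 84 plots, response: carbon_gc_m2
#>   trend coefficients:
#> (Intercept)        ndvi
#>    15.99354    45.59379
#>   residual variogram: exponential (c0 = 33.11, c1 = 75.24, a = 2638 m)
#>   standardized coefficients (|beta_k| sd(q_k)/sd(y)):
#>   ndvi
#> 0.6582
#>   in-sample trend R2: 0.4332
#>   variogram candidates (weighted SSE):
#>     exponential 10.5007
#>     gaussian    12.1315
#>     spherical   11.027

typical <- plots[plots$stratum == "typical", ]
loocv(typical, carbon_gc_m2 ~ ndvi, "RK", family = "exponential")
#> LOOCV [RK/exponential] on 55 plots (ndvi): R2 = 0.549, MAE = 6.01, RMSE = 7.42 gC/m2
loocv(typical, carbon_gc_m2 ~ ndvi, "LR")
#> LOOCV [LR] on 55 plots (ndvi): R2 = 0.278, MAE = 7.36, RMSE = 9.40 gC/m2
```

The trend explains less than half the variance on its own; the residual
variogram shows strong spatial structure (partial sill ≈ 70% of the total
sill at a ≈ 2.6 km range), and kriging that structure cuts the held-out
RMSE from 9.40 to 7.42 gC/m² — the characteristic RK-over-LR gain on
spatially structured fields.

Regional accounting from a published per-class summary (area in 10⁴ hm²,
mean density in gC/m²) closes the unit chain to totals and proportions:

```r
carbon_accounting(chenbarhu_zonal())
#>               class area_1e4_hm2 mean_gc_m2 total_1e4_Mg proportion_pct
#> 1    lowland_meadow        29.36      52.75       15.487         19.414
#> 2  temperate_meadow        63.43      63.02       39.974         50.109
#> 3 temperate_typical        63.74      32.83       20.926         26.232
#> 4             sandy        11.61      29.17        3.387          4.245
#> 5               all       168.14      47.44       79.773        100.000
```

i.e. a total grassland stock of 79.77 × 10⁴ Mg C at a mean density of
47.44 gC/m², with the temperate meadow steppe holding half of the region's
carbon.

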