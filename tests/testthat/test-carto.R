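mk_map <- function(vals, pixel = 30) {
  structure(list(values = vals, xmin = 0, ymax = nrow(vals) * pixel,
                 pixel = pixel, crs = "test", nodata = -9999,
                 n_clamped = 0L, provenance = list()),
            class = "carbon_map")
}

test_that("zonal accounting follows the pinned unit chain", {
  vals <- matrix(c(10, 20, 30, 40), 2, 2)
  classes <- matrix(1L, 2, 2)
  zs <- zonal_summary(mk_map(vals), classes,
                      class_names = c(lowland_meadow = 1L))
  row <- zs[zs$class == "lowland_meadow", ]
  expect_equal(row$mean_gc_m2, 25)
  expect_equal(row$total_1e4_Mg * 1e4, 0.09)       # 100 g/m2 * 900 m2 * 4 px
  expect_equal(row$area_1e4_hm2 * 1e4, 0.36)       # 4 * 900 m2 in hm2
  expect_equal(row$min_gc_m2, 10)
  expect_equal(row$max_gc_m2, 40)
  expect_equal(row$proportion_pct, 100)
})

test_that("per-class totals close against the all row, symmetric cases split 50/50", {
  set.seed(61)
  vals <- matrix(runif(64, 0, 100), 8, 8)
  classes <- matrix(rep(c(1L, 2L), each = 32), 8, 8)
  zs <- zonal_summary(mk_map(vals), classes,
                      class_names = c(a = 1L, b = 2L))
  cls <- zs[zs$class != "all", ]
  all_row <- zs[zs$class == "all", ]
  expect_equal(sum(cls$total_1e4_Mg), all_row$total_1e4_Mg)
  expect_equal(all_row$mean_gc_m2,
               all_row$total_1e4_Mg * 1e10 / (all_row$area_1e4_hm2 * 1e8))
  expect_equal(sum(cls$proportion_pct), 100)

  sym <- matrix(c(rep(10, 32), rep(10, 32)), 8, 8)
  zs <- zonal_summary(mk_map(sym), classes, class_names = c(a = 1L, b = 2L))
  expect_equal(zs$proportion_pct[zs$class != "all"], c(50, 50))

  zs0 <- expect_warning(
    zonal_summary(mk_map(matrix(0, 8, 8)), classes,
                  class_names = c(a = 1L, b = 2L)),
    "proportions set to 0")
  expect_true(all(zs0$total_1e4_Mg == 0))

  # pixel enumeration order does not matter: permuting class labels'
  # positions jointly with values leaves class stats unchanged
  p <- sample(64)
  vals2 <- matrix(vals[p], 8, 8); cl2 <- matrix(classes[p], 8, 8)
  a <- zonal_summary(mk_map(vals), classes, class_names = c(a = 1L, b = 2L))
  b <- zonal_summary(mk_map(vals2), cl2, class_names = c(a = 1L, b = 2L))
  expect_equal(a$total_1e4_Mg, b$total_1e4_Mg)
})

test_that("tabulated accounting reproduces published regional values", {
  acc <- carbon_accounting(chenbarhu_zonal())
  all_row <- acc[acc$class == "all", ]
  expect_equal(round(all_row$total_1e4_Mg, 2), 79.77)
  expect_equal(round(all_row$mean_gc_m2, 2), 47.44)
  expect_equal(round(acc$proportion_pct[acc$class == "temperate_meadow"], 2),
               50.11)
})

test_that("mosaic unions disjoint maps and rejects overlap", {
  v1 <- matrix(c(1, NA, 3, NA), 2, 2)
  v2 <- matrix(c(NA, 2, NA, 4), 2, 2)
  m <- mosaic(list(mk_map(v1), mk_map(v2)))
  expect_equal(m$values, matrix(c(1, 2, 3, 4), 2, 2))
  expect_identical(mosaic(list(mk_map(v1)))$values, v1)

  v3 <- v2; v3[1, 1] <- 9  # overlaps v1 at (1,1)
  expect_error(mosaic(list(mk_map(v1), mk_map(v3))),
               "overlapping valid pixels; first at row 1, col 1")
  small <- mk_map(matrix(1, 3, 3))
  expect_error(mosaic(list(mk_map(v1), small)), "common grid")
})

test_that("per-class histograms are normalized fractions", {
  vals <- matrix(50, 4, 4)
  classes <- matrix(1L, 4, 4)
  h <- histogram_by_class(mk_map(vals), classes, c(0, 40, 80, 120),
                          class_names = c(a = 1L))
  expect_equal(h$fraction, c(0, 1, 0))

  set.seed(62)
  vals <- matrix(runif(10000, 0, 100), 100, 100)
  classes <- matrix(1L, 100, 100)
  h <- histogram_by_class(mk_map(vals), classes, seq(0, 100, by = 20),
                          class_names = c(a = 1L))
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  expect_true(all(abs(h$fraction - 0.2) < 0.03))
})

test_that("stratum maps evaluate the model at masked pixel centres", {
  cfg <- synthetic_config(extent = c(0, 960, 0, 960), seed = 8,
                          trend_coeffs = c(NDVI = 60))
  fx <- make_fixture_stack(cfg, ndvi_const = 0.5)
  pl <- simulate_plots(cfg)  # point-level covariate (non-constant)
  fit <- rk(carbon_gc_m2 ~ NDVI, pl, family = "exponential",
            stratum = "typical")
  fit$variogram <- pure_nugget(5)
  map <- predict_stratum_map(fit, fx$stack, fx$classes)
  # constant covariate + pure nugget: map is the constant LR value
  lr_val <- max(unname(fit$trend[1] + fit$trend[2] * 0.5), 0)
  valid <- map$values[!is.na(map$values)]
  expect_lt(max(abs(valid - lr_val)), 1e-8)
  # meadow pixels (east half) excluded
  expect_true(all(is.na(map$values[, 17:32])))
  expect_false(any(is.na(map$values[, 1:16])))
})

test_that("end-to-end map error stays below the residual sill", {
  cfg <- synthetic_config(extent = c(0, 960, 0, 960), seed = 9,
                          trend_coeffs = c(NDVI = 60),
                          true_variogram = vgm_model("exponential", 20, 80,
                                                     range = 240))
  fx <- make_fixture_stack(cfg)
  pl <- simulate_plots(cfg, stack = fx$stack)
  maps <- lapply(c("typical", "meadow"), function(s) {
    fit <- rk(carbon_gc_m2 ~ NDVI, pl[pl$stratum == s, ],
              family = "exponential", stratum = s, n_bins = 10)
    predict_stratum_map(fit, fx$stack, fx$classes)
  })
  full <- mosaic(maps)
  truth <- pmax(cfg$trend_intercept + 60 * fx$ndvi, 0)  # noise-free trend
  err <- full$values - truth
  rmse <- sqrt(mean(err^2, na.rm = TRUE))
  expect_lt(rmse, sqrt(100))  # below the residual sill (sd 10 gC/m2)
})

test_that("carbon maps round-trip through ASCII grid files", {
  vals <- matrix(c(1.5, NA, 3.25, 4), 2, 2)
  path <- withr::local_tempfile(fileext = ".asc")
  write_carbon_map(mk_map(vals), path)
  m2 <- read_carbon_map(path)
  expect_equal(m2$values, vals)
  expect_equal(m2$pixel, 30)
  expect_equal(m2$ymax, 60)
})
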