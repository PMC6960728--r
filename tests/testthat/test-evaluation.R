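test_that("metrics match hand-computed values", {
  m <- rk_metrics(c(0, 2), c(1, 1))
  expect_equal(m$r2, 0)
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)

  obs <- c(3, 7, 1, 9)
  perfect <- rk_metrics(obs, obs)
  expect_equal(unlist(perfect), c(r2 = 1, mae = 0, rmse = 0))

  expect_equal(rk_metrics(obs, rep(mean(obs), 4))$r2, 0)
  expect_error(rk_metrics(c(2, 2), c(1, 3)), "undefined")
  m <- rk_metrics(c(2, 2), c(1, 3), allow_constant_obs = TRUE)
  expect_true(is.na(m$r2) && m$mae == 1)
})

test_that("rmse >= mae for arbitrary prediction vectors", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    m <- rk_metrics(rnorm(n), rnorm(n))
    expect_gte(m$rmse, m$mae)
    expect_lte(m$r2, 1)
  }
})

test_that("Pearson screening recovers exact and destroyed correlations", {
  pl <- toy_plots(30, sd = 0)          # y = 3 + 2q exactly
  tab <- pearson_screen(pl, "q")
  expect_equal(tab$r, rep(1, 3), tolerance = 1e-12)
  expect_true(all(tab$significant))
  expect_setequal(tab$group, c("all", "typical", "meadow"))

  pl$neg <- -pl$carbon_gc_m2
  tab <- pearson_screen(pl, "neg")
  expect_equal(tab$r[tab$group == "all"], -1, tolerance = 1e-12)

  pl$flat <- 1
  expect_error(pearson_screen(pl, "flat"), "zero-variance")

  # permuting the covariate destroys a strong correlation
  set.seed(42)
  pl84 <- simulate_plots(synthetic_config(seed = 2))
  r0 <- abs(cor(pl84$ndvi, pl84$carbon_gc_m2))
  weaker <- vapply(1:40, function(i) {
    abs(cor(sample(pl84$ndvi), pl84$carbon_gc_m2)) < r0
  }, logical(1))
  expect_gte(mean(weaker), 0.95)
})

test_that("LOOCV of the LR baseline equals a brute-force fold loop", {
  pl <- toy_plots(15, sd = 2)
  cv <- loocv(pl, carbon_gc_m2 ~ q, method = "LR")
  # independent oracle: plain lm / predict per fold
  pred <- vapply(seq_len(15), function(i) {
    fit <- lm(carbon_gc_m2 ~ q, data = pl[-i, ])
    unname(predict(fit, newdata = pl[i, ]))
  }, numeric(1))
  expect_equal(cv$pred, pred, tolerance = 1e-10)
  expect_equal(cv$obs, pl$carbon_gc_m2)
  m <- rk_metrics(pl$carbon_gc_m2, pred)
  expect_equal(cv$rmse, m$rmse)

  # exact linear response: every fold predicts exactly
  exact <- loocv(toy_plots(12, sd = 0), carbon_gc_m2 ~ q, method = "LR")
  expect_equal(c(exact$r2, exact$mae, exact$rmse), c(1, 0, 0),
               tolerance = 1e-10)
})

test_that("LOOCV is invariant to covariate affine rescaling (LR)", {
  pl <- toy_plots(14, sd = 2)
  a <- loocv(pl, carbon_gc_m2 ~ q, method = "LR")
  pl$q <- 3 * pl$q - 2
  b <- loocv(pl, carbon_gc_m2 ~ q, method = "LR")
  expect_equal(a$pred, b$pred, tolerance = 1e-9)
})

test_that("RK and LR LOOCV agree under a pure-nugget residual model", {
  pl <- toy_plots(20, sd = 3)
  lr <- loocv(pl, carbon_gc_m2 ~ q, method = "LR")
  rk_cv <- loocv(pl, carbon_gc_m2 ~ q, method = "RK",
                 variogram = pure_nugget(9))
  expect_lt(max(abs(rk_cv$pred - lr$pred)), 1e-8)
  expect_lt(abs(rk_cv$rmse - lr$rmse), 1e-6)
  expect_lt(abs(rk_cv$mae - lr$mae), 1e-6)
})

test_that("pooling concatenates folds and recomputes metrics", {
  cv1 <- structure(list(obs = 0, pred = 1, stratum = "typical",
                        plot_id = "a", method = "RK", family = "exponential",
                        covariates = "q"), class = "rk_cv")
  cv2 <- structure(list(obs = 2, pred = 1, stratum = "meadow",
                        plot_id = "b", method = "RK", family = "gaussian",
                        covariates = "q"), class = "rk_cv")
  pooled <- combine_strata_cv(cv1, cv2)
  expect_length(pooled$obs, 2)
  expect_equal(c(pooled$r2, pooled$mae, pooled$rmse), c(0, 1, 1))

  cv2$plot_id <- "a"
  expect_error(combine_strata_cv(cv1, cv2), "overlapping plot ids")

  perf <- structure(list(obs = c(1, 2), pred = c(1, 2), stratum = "typical",
                         plot_id = c("c", "d"), method = "LR",
                         family = NA_character_, covariates = "q"),
                    class = "rk_cv")
  perf2 <- perf; perf2$plot_id <- c("e", "f"); perf2$stratum <- "meadow"
  perf2$obs <- c(4, 6); perf2$pred <- c(4, 6)
  pooled <- combine_strata_cv(perf, perf2)
  expect_equal(c(pooled$r2, pooled$mae, pooled$rmse), c(1, 0, 0))
})

test_that("model selection ranks by R2 with RMSE/MAE tie-breaks", {
  mk <- function(r2, rmse, mae, stratum = "typical", fam = "exponential") {
    structure(list(obs = 1:2, pred = 2:3, stratum = rep(stratum, 2),
                   plot_id = NULL, method = "RK", family = fam,
                   covariates = "q", r2 = r2, mae = mae, rmse = rmse),
              class = "rk_cv")
  }
  tab <- model_selection(list(mk(0.5, 9, 5, fam = "gaussian"),
                              mk(0.5, 10, 4)))
  expect_true(tab$selected[tab$family == "gaussian"])  # rmse 9 beats 10
  single <- model_selection(list(mk(0.2, 1, 1, stratum = "meadow")))
  expect_true(single$selected)
  expect_error(model_selection(list()), "no cross-validation results")
})
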