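test_that("OLS trend matches hand computation and stores residuals", {
  d <- data.frame(x = c(0, 1, 2), y = c(0, 0, 0), q = c(0, 1, 2),
                  carbon = c(0, 1, 2))
  tr <- steppeRK:::fit_trend_ols(carbon ~ q, d)
  expect_equal(unname(tr$coefficients), c(0, 1), tolerance = 1e-12)
  expect_equal(tr$residuals, rep(0, 3), tolerance = 1e-12)

  # OLS with intercept: residuals sum to zero
  pl <- toy_plots(30, sd = 2)
  tr <- steppeRK:::fit_trend_ols(carbon_gc_m2 ~ q, pl)
  expect_lt(abs(sum(tr$residuals)), 1e-8)
})

test_that("rank-deficient designs error naming the collinear column", {
  pl <- toy_plots(20, sd = 1)
  pl$q2 <- 2 * pl$q + 1
  expect_error(steppeRK:::fit_trend_ols(carbon_gc_m2 ~ q + q2, pl),
               "collinear column\\(s\\): q2")
  pl$const <- 5
  expect_error(steppeRK:::fit_trend_ols(carbon_gc_m2 ~ q + const, pl),
               "const")
})

test_that("standardized coefficients are invariant to covariate rescaling", {
  pl <- toy_plots(40, sd = 3)
  set.seed(7); pl$w <- rnorm(40)
  f1 <- rk(carbon_gc_m2 ~ q + w, pl, family = "exponential")
  pl2 <- pl
  pl2$q <- 100 * pl$q - 17  # affine rescale
  f2 <- rk(carbon_gc_m2 ~ q + w, pl2, family = "exponential")
  expect_equal(unname(f1$std_coefficients), unname(f2$std_coefficients),
               tolerance = 1e-10)
})

test_that("pure-nugget RK collapses to the LR trend off-sample", {
  pl <- toy_plots(30, sd = 4)
  fit <- rk(carbon_gc_m2 ~ q, pl, family = "exponential")
  fit$variogram <- pure_nugget(5)
  new <- data.frame(q = runif(6), x = runif(6, 2000, 3000),
                    y = runif(6, 2000, 3000))
  expect_lt(max(abs(predict(fit, new, type = "rk") -
                    predict(fit, new, type = "trend"))), 1e-8)
})

test_that("RK with zero nugget reproduces training observations", {
  pl <- toy_plots(25, sd = 4)
  fit <- rk(carbon_gc_m2 ~ q, pl, family = "exponential")
  fit$variogram <- vgm_model("exponential", 0, 25, 400)
  pred <- predict(fit, pl, type = "rk")
  expect_lt(max(abs(pred - pl$carbon_gc_m2) / abs(pl$carbon_gc_m2)), 1e-6)
})

test_that("far-field prediction reverts to the trend", {
  # samples mutually beyond a spherical range: equal kriging weights, and
  # OLS residuals average zero, so the residual term vanishes
  pl <- toy_plots(12, sd = 4)
  pl$x <- seq(0, by = 500, length.out = 12); pl$y <- 0
  fit <- rk(carbon_gc_m2 ~ q, pl, family = "exponential")
  fit$variogram <- vgm_model("spherical", 2, 10, 300)
  new <- data.frame(q = 0.4, x = 1e6, y = 1e6)
  expect_lt(abs(predict(fit, new, "rk") - predict(fit, new, "trend")), 1e-6)
})

test_that("RK decomposes exactly into trend plus kriged residual", {
  pl <- toy_plots(30, sd = 5)
  fit <- rk(carbon_gc_m2 ~ q, pl, family = "spherical")
  new <- data.frame(q = runif(5), x = runif(5, 0, 1000),
                    y = runif(5, 0, 1000))
  ok <- ok_predict_points(fit$coords, fit$residuals, fit$variogram,
                          as.matrix(new[, c("x", "y")]))
  expect_equal(predict(fit, new, "rk"),
               predict(fit, new, "trend") + ok$prediction)
})

test_that("family = 'all' returns three candidates with their WSSE", {
  pl <- toy_plots(40, sd = 5)
  fit <- rk(carbon_gc_m2 ~ q, pl, family = "all")
  expect_named(fit$candidates, c("exponential", "gaussian", "spherical"))
  expect_true(all(vapply(fit$candidates,
                         function(m) is.finite(m$wsse), logical(1))))
  expect_identical(fit$variogram$kind,
                   attr(fit$candidates, "best_wsse"))
})

test_that("variable importance ranks by |standardized coefficient|", {
  set.seed(9)
  n <- 60
  q1 <- rnorm(n); q2 <- rnorm(n)  # independent, approx orthogonal
  d <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                  a = q1, b = q2, carbon = 2 * scale(q1) + 1 * scale(q2) +
                    rnorm(n, sd = 0.1))
  fit <- rk(carbon ~ a + b, d, family = "exponential")
  vi <- variable_importance(fit)
  expect_equal(vi$covariate, c("a", "b"))
  expect_equal(vi$rank, 1:2)
  # exact tie: alphabetical
  fit2 <- fit
  fit2$std_coefficients <- c(b = 0.5, a = 0.5)
  expect_equal(variable_importance(fit2)$covariate, c("a", "b"))
  fit3 <- fit; fit3$p <- 1L
  expect_error(variable_importance(fit3), "p >= 2")
})

test_that("model JSON round-trips with identical predictions", {
  pl <- toy_plots(25, sd = 3)
  fit <- rk(carbon_gc_m2 ~ q, pl, family = "gaussian", stratum = "typical")
  path <- withr::local_tempfile(fileext = ".json")
  rk_to_json(fit, path)
  fit2 <- rk_from_json(path)
  new <- data.frame(q = runif(4), x = runif(4, 0, 1000),
                    y = runif(4, 0, 1000))
  expect_equal(predict(fit2, new, "rk"), predict(fit, new, "rk"),
               tolerance = 1e-12)
  expect_identical(fit2$stratum, "typical")
})

test_that("excluded plots are dropped before fitting", {
  pl <- toy_plots(25, sd = 3)
  pl$excluded <- c(TRUE, rep(FALSE, 24))
  expect_message(fit <- rk(carbon_gc_m2 ~ q, pl, family = "exponential"),
                 "dropping 1 plot")
  expect_equal(fit$n, 24L)
})
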