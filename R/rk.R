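#' Fit a regression-kriging model
#'
#' Two-step regression kriging: an ordinary-least-squares trend of the
#' response on the covariates, followed by variogram modelling of the OLS
#' residuals. Predictions (see [predict.rk()]) sum the trend and the
#' ordinary-kriging interpolation of the residuals,
#' \deqn{\hat z_{RK}(s_0) = \sum_{k=0}^p \hat\beta_k q_k(s_0) +
#'       \sum_{i=1}^n \lambda_i e(s_i),}
#' the standard hybrid of a linear regression on auxiliary predictors with
#' OK of its residuals. The trend is deliberately plain OLS (not GLS): the
#' procedure is sequential by construction.
#'
#' @param formula model formula, e.g. `carbon_gc_m2 ~ ndvi`; additive terms
#'   in covariate columns of `data`.
#' @param data data.frame containing the response, covariates and
#'   coordinate columns. Rows with an `excluded` column set to `TRUE`
#'   (nodata covariates) are dropped with a message.
#' @param coords character vector of length 2 naming the projected
#'   coordinate columns (m); default `c("x", "y")`.
#' @param family residual variogram family: one of `"exponential"`,
#'   `"gaussian"`, `"spherical"`, or `"all"` to fit all three candidates
#'   (the one with the lowest weighted SSE becomes the active model;
#'   downstream cross-validation can re-select, see [model_selection()]).
#' @param n_bins,max_lag passed to [empirical_variogram()].
#' @param stratum optional label carried in the fitted object.
#' @return an object of class `"rk"` with components `trend`
#'   (coefficients), `std_coefficients`, `residuals`, `coords`,
#'   `variogram`, `candidates`, `empirical`, `n`, `p`.
#' @examples
#' cfg <- synthetic_config(seed = 7)
#' plots <- simulate_plots(cfg)
#' fit <- rk(carbon_gc_m2 ~ ndvi, plots, family = "exponential")
#' fit
#' @export
rk <- function(formula, data, coords = c("x", "y"),
               family = c("exponential", "gaussian", "spherical", "all"),
               n_bins = 15, max_lag = NULL, stratum = NULL) {
  family <- match.arg(family)
  stopifnot(length(coords) == 2L, all(coords %in% names(data)))
  if (!is.null(data$excluded) && any(data$excluded)) {
    message(sprintf("dropping %d plot(s) with nodata covariates",
                    sum(data$excluded)))
    data <- data[!data$excluded, , drop = FALSE]
  }
  tr <- fit_trend_ols(formula, data)
  xy <- as.matrix(data[, coords])

  emp <- empirical_variogram(xy, tr$residuals, n_bins = n_bins,
                             max_lag = max_lag)
  if (family == "all") {
    candidates <- fit_all_variograms(emp)
    vg <- candidates[[attr(candidates, "best_wsse")]]
  } else {
    vg <- fit_variogram(emp, family)
    candidates <- stats::setNames(list(vg), family)
  }

  structure(list(
    call = match.call(),
    formula = formula,
    terms = tr$terms,
    trend = tr$coefficients,
    std_coefficients = tr$std_coefficients,
    residuals = tr$residuals,
    fitted_trend = tr$fitted,
    coords = xy,
    coord_names = coords,
    variogram = vg,
    candidates = candidates,
    empirical = emp,
    stratum = stratum,
    response = tr$response,
    covariates = tr$covariates,
    n = tr$n, p = tr$p
  ), class = "rk")
}

# OLS trend with an intercept; hard error on rank deficiency, naming the
# offending columns rather than silently dropping them.
fit_trend_ols <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  tt <- stats::terms(mf)
  mm <- stats::model.matrix(tt, mf)
  if (attr(tt, "intercept") != 1L)
    stop("the trend model must include an intercept")
  n <- nrow(mm); p <- ncol(mm) - 1L
  if (p < 1L) stop("at least one covariate is required")
  if (n <= p + 1L) stop("need n > p + 1 samples to fit the trend")
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1L):ncol(mm)]]
    stop("rank-deficient trend design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrm, y)
  fitted <- as.numeric(mm %*% beta)
  res <- as.numeric(y - fitted)
  covs <- colnames(mm)[-1L]
  sdy <- stats::sd(y)
  stdc <- vapply(covs, function(k) beta[[k]] * stats::sd(mm[, k]) / sdy,
                 numeric(1))
  list(coefficients = beta, std_coefficients = stdc, residuals = res,
       fitted = fitted, terms = tt, n = n, p = p,
       response = as.character(formula[[2L]]), covariates = covs)
}

#' @export
print.rk <- function(x, ...) {
  cat("Regression-kriging model")
  if (!is.null(x$stratum)) cat(sprintf(" [stratum: %s]", x$stratum))
  cat(sprintf("\n  n = %d plots, response: %s\n", x$n, x$response))
  cat("  trend coefficients:\n")
  print(round(x$trend, 6))
  cat(sprintf("  residual variogram: %s (c0 = %.4g, c1 = %.4g, a = %.4g m)\n",
              x$variogram$kind, x$variogram$nugget, x$variogram$psill,
              x$variogram$range))
  invisible(x)
}

#' @export
summary.rk <- function(object, ...) {
  structure(list(model = object), class = "summary.rk")
}

#' @export
print.summary.rk <- function(x, ...) {
  m <- x$model
  print(m)
  cat("  standardized coefficients (|beta_k| sd(q_k)/sd(y)):\n")
  print(round(m$std_coefficients, 4))
  rss <- sum(m$residuals^2)
  y <- m$fitted_trend + m$residuals
  cat(sprintf("  in-sample trend R2: %.4f\n",
              1 - rss / sum((y - mean(y))^2)))
  if (length(m$candidates) > 1L) {
    cat("  variogram candidates (weighted SSE):\n")
    for (k in names(m$candidates))
      cat(sprintf("    %-11s %.6g\n", k, m$candidates[[k]]$wsse))
  }
  invisible(x)
}

#' @export
coef.rk <- function(object, ...) object$trend

#' @export
residuals.rk <- function(object, ...) object$residuals

#' Predict from a regression-kriging model
#'
#' `type = "rk"` (default) returns trend + ordinary-kriging residual
#' interpolation; `type = "trend"` returns the linear-regression trend
#' alone (the LR baseline). Targets whose covariates are nodata (`NA`)
#' yield `NA` predictions.
#'
#' @param object an [rk()] fit.
#' @param newdata data.frame with the covariate columns; for `type = "rk"`
#'   it must also carry the coordinate columns used at fit time (or supply
#'   `targets`).
#' @param type `"rk"` or `"trend"`.
#' @param targets optional two-column matrix of prediction coordinates,
#'   overriding the coordinate columns of `newdata`.
#' @param ... unused.
#' @return numeric vector of predicted carbon density (gC/m2).
#' @export
predict.rk <- function(object, newdata, type = c("rk", "trend"),
                       targets = NULL, ...) {
  type <- match.arg(type)
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  tt <- stats::delete.response(object$terms)
  mm <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                   na.action = stats::na.pass))
  trend <- as.numeric(mm %*% object$trend[colnames(mm)])
  if (type == "trend") return(trend)
  if (is.null(targets)) {
    if (!all(object$coord_names %in% names(newdata)))
      stop("newdata must carry coordinate columns ",
           paste(object$coord_names, collapse = ", "),
           " (or pass `targets`)")
    targets <- as.matrix(newdata[, object$coord_names])
  }
  ok <- ok_predict_points(object$coords, object$residuals,
                          object$variogram, targets)
  trend + ok$prediction
}

#' Rank covariates by standardized-coefficient importance
#'
#' For a multivariate trend, covariates are ranked by the absolute value of
#' the standardized coefficient `|beta_k| * sd(q_k) / sd(y)` in descending
#' order; ties are broken alphabetically by covariate name.
#'
#' @param object an [rk()] fit with at least two covariates.
#' @return data.frame with columns `covariate`, `std_coefficient`
#'   (absolute value) and `rank`.
#' @export
variable_importance <- function(object) {
  stopifnot(inherits(object, "rk"))
  if (object$p < 2L)
    stop("variable importance needs a multivariate trend (p >= 2)")
  a <- abs(object$std_coefficients)
  ord <- order(-a, names(a))
  data.frame(covariate = names(a)[ord],
             std_coefficient = unname(a[ord]),
             rank = seq_along(a),
             stringsAsFactors = FALSE)
}

#' Plot an rk model's residual variogram
#'
#' Empirical semivariogram points (sized by pair count) with the fitted
#' model curve(s) overlaid.
#'
#' @param x an [rk()] fit.
#' @param ... passed to [plot()].
#' @export
plot.rk <- function(x, ...) {
  emp <- x$empirical
  h <- seq(0, max(emp$lag), length.out = 200)
  graphics::plot(emp$lag, emp$gamma, pch = 16,
       cex = 0.6 + emp$n_pairs / max(emp$n_pairs),
       xlab = "lag distance h (m)",
       ylab = expression(gamma(h) ~ "(gC/m2)"^2),
       ylim = c(0, max(emp$gamma) * 1.1),
       main = sprintf("Residual semivariogram (%s fit)", x$variogram$kind),
       ...)
  graphics::lines(h, vgm_semivariance(x$variogram, h), lwd = 2)
  invisible(x)
}

#' Serialize / restore an rk model as JSON
#'
#' Stores the trend coefficients, covariate names, fitted variogram, sample
#' coordinates and residuals, so predictions are reproducible without
#' refitting.
#'
#' @param object an [rk()] fit.
#' @param path optional file path.
#' @return JSON string (invisibly if written to `path`).
#' @export
rk_to_json <- function(object, path = NULL) {
  x <- list(
    formula = deparse(object$formula),
    trend = as.list(object$trend),
    std_coefficients = as.list(object$std_coefficients),
    variogram = list(kind = object$variogram$kind,
                     nugget = object$variogram$nugget,
                     partial_sill = object$variogram$psill,
                     range_a = object$variogram$range),
    coord_names = object$coord_names,
    coords = list(x = as.numeric(object$coords[, 1L]),
                  y = as.numeric(object$coords[, 2L])),
    residuals = object$residuals,
    stratum = object$stratum,
    response = object$response,
    covariates = object$covariates)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname rk_to_json
#' @param json JSON string or file path written by [rk_to_json()].
#' @export
rk_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  f <- stats::as.formula(x$formula)
  coords <- cbind(as.numeric(x$coords$x), as.numeric(x$coords$y))
  obj <- list(
    call = quote(rk_from_json()),
    formula = f,
    terms = stats::terms(f),
    trend = unlist(x$trend),
    std_coefficients = unlist(x$std_coefficients),
    residuals = as.numeric(x$residuals),
    fitted_trend = NULL,
    coords = coords,
    coord_names = x$coord_names,
    variogram = vgm_model(x$variogram$kind, x$variogram$nugget,
                          x$variogram$partial_sill, x$variogram$range_a),
    candidates = NULL, empirical = NULL,
    stratum = x$stratum,
    response = x$response,
    covariates = x$covariates,
    n = nrow(coords), p = length(x$covariates))
  class(obj) <- "rk"
  obj
}
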