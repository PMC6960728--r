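#' Accuracy metrics for carbon-stock predictions
#'
#' Coefficient of determination, mean absolute error and root mean square
#' error of predictions against observations:
#' \deqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2,\quad
#'       MAE = \frac{1}{n}\sum |y_i - \hat y_i|,\quad
#'       RMSE = \sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2}.}
#' MAE and RMSE are reported in the units of the response (gC/m2 here).
#' With constant observations \eqn{R^2} is undefined and an error is
#' raised unless `allow_constant_obs = TRUE`, in which case `r2 = NA` and
#' MAE/RMSE are still returned.
#'
#' @param obs,pred numeric vectors of equal length `>= 2`.
#' @param allow_constant_obs return `r2 = NA` instead of erroring when
#'   `obs` has zero variance.
#' @return named list `r2`, `mae`, `rmse`.
#' @examples
#' rk_metrics(c(0, 2), c(1, 1))  # r2 = 0, mae = 1, rmse = 1
#' @export
rk_metrics <- function(obs, pred, allow_constant_obs = FALSE) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2L,
            all(is.finite(obs)), all(is.finite(pred)))
  err <- obs - pred
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) {
    if (!allow_constant_obs)
      stop("R2 is undefined for constant observations")
    return(list(r2 = NA_real_, mae = mae, rmse = rmse))
  }
  list(r2 = 1 - sum(err^2) / sst, mae = mae, rmse = rmse)
}

#' Pearson correlation screening of candidate covariates
#'
#' Pearson r between each candidate covariate and the response, computed
#' for all plots pooled and within each stratum, with a two-sided p-value
#' from the t statistic \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` df
#' (via [stats::cor.test()]) and a significance flag at `p < 0.01`
#' (no multiple-testing correction).
#'
#' @param plots plot table with the response, covariates and a `stratum`
#'   column (`"typical"` / `"meadow"`).
#' @param candidates character vector of covariate column names.
#' @param response response column name.
#' @return data.frame with one row per covariate x group, columns
#'   `covariate`, `group`, `n`, `r`, `p_value`, `significant`.
#' @export
pearson_screen <- function(plots, candidates,
                           response = "carbon_gc_m2") {
  stopifnot(response %in% names(plots), all(candidates %in% names(plots)))
  groups <- c(list(all = rep(TRUE, nrow(plots))),
              lapply(stats::setNames(nm = unique(plots$stratum)),
                     function(s) plots$stratum == s))
  rows <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (sum(sel) < 3L) stop("need n >= 3 plots in group ", g)
    y <- plots[[response]][sel]
    for (cv in candidates) {
      q <- plots[[cv]][sel]
      if (stats::sd(q) == 0) stop("zero-variance covariate: ", cv)
      ct <- stats::cor.test(q, y, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, group = g, n = sum(sel),
        r = unname(ct$estimate), p_value = ct$p.value,
        significant = ct$p.value < 0.01,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Leave-one-out cross-validation of LR and RK predictors
#'
#' For each plot i the trend is refit on the remaining n - 1 plots and the
#' held-out plot predicted; for `method = "RK"` the per-fold residuals are
#' kriged to the held-out location. The residual variogram is, by default,
#' fitted once on the full-sample residuals and held fixed across folds
#' (`variogram_policy = "fixed"`); `"refit"` re-estimates it inside every
#' fold (slower, and unstable with 15 bins on n - 1 points).
#'
#' @param plots plot table (rows with `excluded == TRUE` are dropped).
#' @param formula trend formula, e.g. `carbon_gc_m2 ~ ndvi`.
#' @param method `"LR"` (trend only) or `"RK"`.
#' @param family variogram family for RK (`"exponential"`, `"gaussian"`,
#'   `"spherical"`).
#' @param coords coordinate column names.
#' @param variogram_policy `"fixed"` or `"refit"`.
#' @param variogram optional [vgm_model()]; if supplied it is used as the
#'   (fixed) residual variogram in every fold instead of being estimated,
#'   e.g. to study kriging behaviour under a known model.
#' @param n_bins,max_lag passed to [empirical_variogram()].
#' @return an object of class `"rk_cv"`: list with `obs`, `pred`,
#'   `stratum`, `plot_id`, `method`, `family`, `covariates` and metrics
#'   `r2`, `mae`, `rmse`.
#' @export
loocv <- function(plots, formula, method = c("LR", "RK"),
                  family = "exponential", coords = c("x", "y"),
                  variogram_policy = c("fixed", "refit"),
                  variogram = NULL,
                  n_bins = 15, max_lag = NULL) {
  method <- match.arg(method)
  variogram_policy <- match.arg(variogram_policy)
  if (!is.null(plots$excluded)) plots <- plots[!plots$excluded, , drop = FALSE]
  n <- nrow(plots)
  if (n < 10L) stop("LOOCV needs at least 10 plots")

  full_vgm <- NULL
  if (!is.null(variogram)) {
    stopifnot(inherits(variogram, "vgm_model"))
    full_vgm <- variogram
    variogram_policy <- "fixed"
  } else if (method == "RK" && variogram_policy == "fixed") {
    full <- rk(formula, plots, coords = coords, family = family,
               n_bins = n_bins, max_lag = max_lag)
    full_vgm <- full$variogram
  }

  obs <- numeric(n); pred <- numeric(n)
  for (i in seq_len(n)) {
    train <- plots[-i, , drop = FALSE]
    test <- plots[i, , drop = FALSE]
    fold <- tryCatch({
      tr <- fit_trend_ols(formula, train)
      tt <- stats::delete.response(tr$terms)
      mmi <- stats::model.matrix(tt, stats::model.frame(tt, test))
      p_trend <- as.numeric(mmi %*% tr$coefficients[colnames(mmi)])
      if (method == "LR") {
        p_trend
      } else {
        xy <- as.matrix(train[, coords])
        vg <- if (variogram_policy == "fixed") full_vgm else {
          fit_variogram(empirical_variogram(xy, tr$residuals,
                                            n_bins = n_bins,
                                            max_lag = max_lag), family)
        }
        s <- solve_ok(xy, tr$residuals, vg,
                      as.numeric(test[, coords]))
        p_trend + s$prediction
      }
    }, error = function(e) {
      stop(sprintf("LOOCV fold %d failed: %s", i, conditionMessage(e)))
    })
    obs[i] <- stats::model.response(stats::model.frame(formula, test))
    pred[i] <- fold
  }
  m <- rk_metrics(obs, pred)
  structure(list(obs = obs, pred = pred,
                 stratum = plots$stratum,
                 plot_id = plots$plot_id,
                 method = method,
                 family = if (method == "RK") family else NA_character_,
                 covariates = all.vars(formula[[3L]]),
                 r2 = m$r2, mae = m$mae, rmse = m$rmse),
            class = "rk_cv")
}

#' @export
print.rk_cv <- function(x, ...) {
  cat(sprintf("LOOCV [%s%s] on %d plots (%s): R2 = %.3f, MAE = %.2f, RMSE = %.2f gC/m2\n",
              x$method,
              if (!is.na(x$family)) paste0("/", x$family) else "",
              length(x$obs), paste(x$covariates, collapse = "+"),
              x$r2, x$mae, x$rmse))
  invisible(x)
}

#' Pool per-stratum cross-validation results
#'
#' Concatenates the held-out (obs, pred) pairs of the per-stratum results
#' and recomputes the metrics on the pooled vectors (not a weighted
#' average of per-stratum metrics).
#'
#' @param cv_typical,cv_meadow `"rk_cv"` objects with disjoint plot ids.
#' @return an `"rk_cv"` object for the pooled samples.
#' @export
combine_strata_cv <- function(cv_typical, cv_meadow) {
  stopifnot(inherits(cv_typical, "rk_cv"), inherits(cv_meadow, "rk_cv"))
  if (!is.null(cv_typical$plot_id) && !is.null(cv_meadow$plot_id)) {
    dup <- intersect(cv_typical$plot_id, cv_meadow$plot_id)
    if (length(dup))
      stop("overlapping plot ids between strata: ",
           paste(utils::head(dup, 5), collapse = ", "))
  }
  obs <- c(cv_typical$obs, cv_meadow$obs)
  pred <- c(cv_typical$pred, cv_meadow$pred)
  m <- rk_metrics(obs, pred)
  structure(list(obs = obs, pred = pred,
                 stratum = c(cv_typical$stratum, cv_meadow$stratum),
                 plot_id = c(cv_typical$plot_id, cv_meadow$plot_id),
                 method = paste(unique(c(cv_typical$method, cv_meadow$method)),
                                collapse = "+"),
                 family = NA_character_,
                 covariates = union(cv_typical$covariates,
                                    cv_meadow$covariates),
                 r2 = m$r2, mae = m$mae, rmse = m$rmse),
            class = "rk_cv")
}

#' Select the best model per stratum from cross-validation results
#'
#' Within each stratum (and across methods/families/covariate sets), ranks
#' results by R2 descending, breaking ties by lower RMSE then lower MAE,
#' and returns the comparison table with the winner flagged.
#'
#' @param cv_results list of `"rk_cv"` objects; each needs a scalar
#'   `stratum_label` attribute or a homogeneous `stratum` field.
#' @param labels optional character vector of stratum labels, one per
#'   result (defaults to each result's own stratum field, requiring it to
#'   be homogeneous).
#' @return data.frame (comparison table) with columns `stratum`,
#'   `variable_set`, `method`, `family`, `r2`, `mae_gc_m2`, `rmse_gc_m2`,
#'   `selected`.
#' @export
model_selection <- function(cv_results, labels = NULL) {
  if (length(cv_results) == 0L) stop("no cross-validation results supplied")
  if (is.null(labels)) {
    labels <- vapply(cv_results, function(cv) {
      s <- unique(cv$stratum)
      if (length(s) != 1L) stop("ambiguous stratum; supply `labels`")
      s
    }, character(1))
  }
  tab <- do.call(rbind, lapply(seq_along(cv_results), function(i) {
    cv <- cv_results[[i]]
    data.frame(stratum = labels[i],
               variable_set = paste(cv$covariates, collapse = "+"),
               method = cv$method, family = cv$family,
               r2 = cv$r2, mae_gc_m2 = cv$mae, rmse_gc_m2 = cv$rmse,
               stringsAsFactors = FALSE)
  }))
  tab$selected <- FALSE
  for (s in unique(tab$stratum)) {
    i <- which(tab$stratum == s)
    ord <- i[order(-tab$r2[i], tab$rmse_gc_m2[i], tab$mae_gc_m2[i])]
    tab$selected[ord[1L]] <- TRUE
  }
  tab
}
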