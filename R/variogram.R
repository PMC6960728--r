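#' Theoretical variogram model
#'
#' Constructs a semivariogram model of one of the three classical families.
#' The `range` parameter is the *distance parameter* of the closed form
#' (often written \eqn{a}); for the exponential family the effective range
#' (distance at which 95\% of the sill is reached) is \eqn{3a}, for the
#' Gaussian family \eqn{\sqrt{3}a}, and for the spherical family the range
#' parameter is itself the effective range.
#'
#' @param kind one of `"exponential"`, `"gaussian"`, `"spherical"`.
#' @param nugget nugget variance \eqn{c_0 \ge 0}.
#' @param psill partial sill \eqn{c_1 \ge 0}; total sill is `nugget + psill`.
#' @param range distance parameter \eqn{a > 0}, in the units of the
#'   coordinates (metres throughout this package).
#' @return an object of class `"vgm_model"`.
#' @examples
#' m <- vgm_model("spherical", nugget = 0, psill = 10, range = 100)
#' vgm_semivariance(m, c(0, 50, 100, 200))
#' @export
vgm_model <- function(kind = c("exponential", "gaussian", "spherical"),
                      nugget, psill, range) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(nugget), length(nugget) == 1L, is.finite(nugget),
            is.numeric(psill), length(psill) == 1L, is.finite(psill),
            is.numeric(range), length(range) == 1L, is.finite(range))
  if (nugget < 0) stop("nugget must be >= 0")
  if (psill < 0) stop("partial sill must be >= 0")
  if (range <= 0) stop("range parameter must be > 0")
  structure(
    list(kind = kind, nugget = nugget, psill = psill, range = range),
    class = "vgm_model"
  )
}

#' @export
print.vgm_model <- function(x, ...) {
  cat(sprintf("%s variogram model\n", x$kind))
  cat(sprintf("  nugget c0      : %.6g\n", x$nugget))
  cat(sprintf("  partial sill c1: %.6g\n", x$psill))
  cat(sprintf("  range a        : %.6g m (effective range %.6g m)\n",
              x$range, effective_range(x)))
  invisible(x)
}

#' Effective range of a variogram model
#'
#' Distance at which the model reaches (95\% of) its sill: `3a` for
#' exponential, `sqrt(3)*a` for Gaussian, `a` for spherical.
#'
#' @param model a [vgm_model()].
#' @return effective range in metres.
#' @export
effective_range <- function(model) {
  switch(model$kind,
         exponential = 3 * model$range,
         gaussian    = sqrt(3) * model$range,
         spherical   = model$range)
}

#' Evaluate a variogram model
#'
#' Semivariance \eqn{\gamma(h)} at separation distances `h`, using the
#' convention \eqn{\gamma(0) = 0} (the nugget appears only for `h > 0`).
#'
#' @param model a [vgm_model()].
#' @param h numeric vector of separation distances (m), all `>= 0`.
#' @return numeric vector of semivariances.
#' @export
vgm_semivariance <- function(model, h) {
  stopifnot(inherits(model, "vgm_model"), is.numeric(h))
  if (any(h < 0)) stop("separation distance h must be >= 0")
  c0 <- model$nugget; c1 <- model$psill; a <- model$range
  g <- switch(model$kind,
    exponential = c0 + c1 * (1 - exp(-h / a)),
    gaussian    = c0 + c1 * (1 - exp(-(h / a)^2)),
    spherical   = {
      hr <- pmin(h / a, 1)
      c0 + c1 * (1.5 * hr - 0.5 * hr^3)
    })
  g[h == 0] <- 0
  g
}

#' Stationary covariance implied by a variogram model
#'
#' For a second-order stationary process, `C(h) = (c0 + c1) - gamma(h)`
#' for `h > 0` and `C(0) = c0 + c1`. Used to build covariance matrices for
#' Gaussian-field simulation and as the covariance-form kriging oracle.
#'
#' @inheritParams vgm_semivariance
#' @return numeric vector of covariances.
#' @export
vgm_covariance <- function(model, h) {
  sill <- model$nugget + model$psill
  ifelse(h == 0, sill, sill - vgm_semivariance(model, h))
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Method-of-moments estimator per distance bin:
#' \deqn{\hat\gamma(h) = \frac{1}{2N(h)} \sum_{(i,j) \in h} (z_i - z_j)^2}
#' Pairs are assigned by Euclidean distance to `n_bins` equal-width bins on
#' `(0, max_lag]`; bins with no pairs are dropped.
#'
#' @param coords two-column matrix (or data.frame) of projected x/y in m.
#' @param values numeric vector, one value per row of `coords` (typically
#'   regression residuals in gC/m2).
#' @param n_bins number of distance bins (default 15).
#' @param max_lag maximum lag distance in m; default half the maximum
#'   pairwise distance.
#' @return an object of class `"empirical_variogram"`: a data.frame with
#'   columns `lag` (bin centre, m), `gamma`, `n_pairs`, plus attributes
#'   `max_lag` and `n_bins`.
#' @export
empirical_variogram <- function(coords, values, n_bins = 15, max_lag = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) == length(values),
            all(is.finite(values)), nrow(coords) >= 2L)
  d <- stats::dist(coords)
  if (all(d == 0)) stop("all pairwise distances are zero")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stopifnot(max_lag > 0, n_bins >= 1)

  sqdiff <- as.numeric(stats::dist(matrix(values, ncol = 1)))^2
  dv <- as.numeric(d)
  keep <- dv > 0 & dv <= max_lag
  edges <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- findInterval(dv[keep], edges, left.open = TRUE, all.inside = TRUE)
  np <- tabulate(bin, nbins = n_bins)
  ssq <- vapply(seq_len(n_bins), function(b) sum(sqdiff[keep][bin == b]),
                numeric(1))
  use <- np > 0L
  out <- data.frame(
    lag    = (edges[-1L] + edges[-(n_bins + 1L)])[use] / 2,
    gamma  = ssq[use] / (2 * np[use]),
    n_pairs = np[use]
  )
  structure(out, max_lag = max_lag, n_bins = n_bins,
            class = c("empirical_variogram", "data.frame"))
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf("Empirical semivariogram: %d usable bins, max lag %.6g m\n",
              nrow(x), attr(x, "max_lag")))
  print.data.frame(x, ...)
  invisible(x)
}

# Weighted SSE with Cressie weights w_j = N_j / gamma(h_j)^2, where gamma is
# the *model* semivariance at the bin centre. Bins where the model is ~0 are
# guarded to avoid infinite weights.
vgm_wsse <- function(par, kind, emp) {
  m <- tryCatch(vgm_model(kind, par[1], par[2], par[3]), error = function(e) NULL)
  if (is.null(m)) return(Inf)
  g <- vgm_semivariance(m, emp$lag)
  w <- emp$n_pairs / pmax(g, 1e-10)^2
  sum(w * (emp$gamma - g)^2)
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Bounded weighted least squares minimising
#' \eqn{\sum_j w_j (\hat\gamma_j - \gamma(h_j))^2} with Cressie weights
#' \eqn{w_j = N_j / \gamma(h_j)^2}. Optimised with multi-start L-BFGS-B
#' (starts: `c0 = min(gamma)`, `c1 = max(gamma) - min(gamma)`,
#' `a` in `max_lag` times 1/10, 1/3, 1); bounds `c0, c1 >= 0`,
#' `a` in `(0, 3 * max_lag]`.
#'
#' @param emp an [empirical_variogram()].
#' @param kind variogram family to fit.
#' @return the fitted [vgm_model()] with extra fields `wsse` (the achieved
#'   objective) and `convergence`.
#' @export
fit_variogram <- function(emp, kind = c("exponential", "gaussian", "spherical")) {
  kind <- match.arg(kind)
  stopifnot(inherits(emp, "empirical_variogram"))
  if (nrow(emp) < 3L) stop("need at least 3 usable bins to fit a variogram")
  max_lag <- attr(emp, "max_lag")
  gmin <- min(emp$gamma); gmax <- max(emp$gamma)
  scale <- max(gmax, 1e-8)
  starts <- list()
  for (a0 in max_lag * c(1 / 10, 1 / 3, 1)) {
    starts <- c(starts, list(c(gmin, max(gmax - gmin, 0.1 * scale), a0)))
  }
  # pure-nugget-leaning start for flat empirical variograms
  starts <- c(starts, list(c(mean(emp$gamma), 0.05 * scale, max_lag / 3)))

  lower <- c(0, 0, max_lag * 1e-6)
  upper <- c(Inf, Inf, 3 * max_lag)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lower), upper), vgm_wsse, kind = kind,
                   emp = emp, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("variogram optimisation failed for all starts")
  m <- vgm_model(kind, best$par[1], best$par[2], best$par[3])
  m$wsse <- best$value
  m$convergence <- best$convergence
  m
}

#' Fit all three variogram families
#'
#' Runs [fit_variogram()] for the exponential, Gaussian and spherical
#' families and returns all three candidates with their weighted SSE.
#' Final family selection happens downstream by cross-validation (see
#' [model_selection()]); `best_wsse` here is informational, with ties broken
#' in the order exponential < gaussian < spherical.
#'
#' @param emp an [empirical_variogram()].
#' @return named list of three fitted [vgm_model()]s with attribute
#'   `best_wsse` naming the family with the lowest weighted SSE.
#' @export
fit_all_variograms <- function(emp) {
  fams <- c("exponential", "gaussian", "spherical")
  fits <- lapply(fams, function(k) fit_variogram(emp, k))
  names(fits) <- fams
  wsse <- vapply(fits, function(m) m$wsse, numeric(1))
  attr(fits, "best_wsse") <- fams[which.min(wsse)]  # which.min keeps first on ties
  fits
}

#' Serialize a fitted variogram model to JSON
#'
#' @param model a [vgm_model()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
vgm_to_json <- function(model, path = NULL) {
  x <- list(kind = model$kind, nugget = model$nugget,
            partial_sill = model$psill, range_a = model$range,
            effective_range = effective_range(model),
            wsse = if (is.null(model$wsse)) NA else model$wsse)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname vgm_to_json
#' @param json JSON string or file path produced by [vgm_to_json()].
#' @export
vgm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  m <- vgm_model(x$kind, x$nugget, x$partial_sill, x$range_a)
  if (!is.null(x$wsse) && !is.na(x$wsse)) m$wsse <- x$wsse
  m
}
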