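#' Ordinary kriging at a single target
#'
#' Solves the semivariance-form OK system
#' \deqn{\begin{pmatrix}\Gamma & 1\\ 1^T & 0\end{pmatrix}
#'       \begin{pmatrix}\lambda\\ \mu\end{pmatrix} =
#'       \begin{pmatrix}\gamma_0\\ 1\end{pmatrix}}
#' with \eqn{\Gamma_{ij} = \gamma(\|s_i - s_j\|)} (zero diagonal, the
#' \eqn{\gamma(0)=0} convention, so kriging is non-exact under a nugget) and
#' \eqn{\gamma_{0i} = \gamma(\|s_i - s_0\|)}. The prediction is
#' \eqn{\lambda^T z} and the kriging variance \eqn{\lambda^T\gamma_0 + \mu}.
#'
#' All samples are used (global neighbourhood); duplicate sample
#' coordinates are a hard error rather than being jittered.
#'
#' @param coords two-column matrix of sample x/y (m); rows pairwise distinct.
#' @param values numeric vector of sample values (residuals \eqn{e(s_i)}).
#' @param model a [vgm_model()] for the sampled field.
#' @param target length-2 numeric, the prediction location.
#' @return list with `weights`, `lagrange_mu`, `prediction`,
#'   `kriging_variance`.
#' @examples
#' m <- vgm_model("exponential", nugget = 0, psill = 1, range = 500)
#' xy <- cbind(c(0, 100, 0), c(0, 0, 100))
#' solve_ok(xy, c(1, 2, 3), m, target = c(50, 50))
#' @export
solve_ok <- function(coords, values, model, target) {
  coords <- as.matrix(coords)
  stopifnot(length(target) == 2L)
  sys <- ok_system(coords, values, model)
  g0 <- vgm_semivariance(model, sqrt((coords[, 1] - target[1])^2 +
                                     (coords[, 2] - target[2])^2))
  ok_solve_rhs(sys, g0)
}

# Factorize the OK left-hand side once for reuse over many targets.
ok_system <- function(coords, values, model) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 1L, ncol(coords) == 2L, length(values) == n,
            all(is.finite(values)))
  d <- as.matrix(stats::dist(coords))
  if (n > 1L) {
    off <- d[upper.tri(d)]
    if (any(off == 0)) {
      idx <- which(d == 0 & upper.tri(d), arr.ind = TRUE)[1L, ]
      stop(sprintf("duplicate sample coordinates at rows %d and %d",
                   idx[1], idx[2]))
    }
  }
  G <- matrix(vgm_semivariance(model, as.numeric(d)), n, n)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  list(A_qr = qr(A), values = values, n = n)
}

ok_solve_rhs <- function(sys, g0) {
  n <- sys$n
  sol <- solve(sys$A_qr, c(g0, 1))
  lambda <- sol[seq_len(n)]
  mu <- sol[n + 1L]
  list(weights = lambda,
       lagrange_mu = mu,
       prediction = sum(lambda * sys$values),
       kriging_variance = sum(lambda * g0) + mu)
}

#' Ordinary kriging at many targets
#'
#' Batch form of [solve_ok()]: the \eqn{(n+1)\times(n+1)} system matrix is
#' factorized once and reused for every target.
#'
#' @inheritParams solve_ok
#' @param targets two-column matrix of prediction locations (may have zero
#'   rows, giving empty output).
#' @return list with numeric vectors `prediction` and `variance`, one entry
#'   per target row.
#' @export
ok_predict_points <- function(coords, values, model, targets) {
  coords <- as.matrix(coords)
  targets <- as.matrix(targets)
  if (length(targets) == 0L) {
    return(list(prediction = numeric(0), variance = numeric(0)))
  }
  stopifnot(ncol(targets) == 2L)
  sys <- ok_system(coords, values, model)
  n <- sys$n
  # n x m distance matrix target-to-sample, one LAPACK solve for all targets
  dx <- outer(coords[, 1], targets[, 1], "-")
  dy <- outer(coords[, 2], targets[, 2], "-")
  G0 <- matrix(vgm_semivariance(model, as.numeric(sqrt(dx^2 + dy^2))),
               nrow = n)
  sol <- solve(sys$A_qr, rbind(G0, 1))
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  list(prediction = as.numeric(crossprod(lambda, sys$values)),
       variance = colSums(lambda * G0) + mu)
}
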