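#' Poisson log-likelihood
#'
#' Log-likelihood of counts `y` under independent Poisson observations with
#' means `mu`: \eqn{\ell = \sum_i (y_i \log\mu_i - \mu_i - \log y_i!)}.
#'
#' @param y nonnegative integer counts.
#' @param mu positive Poisson means, recycled against `y`.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(y, mu) {
  stopifnot(length(y) > 0, all(y >= 0), all(is.finite(y)))
  mu <- rep_len(mu, length(y))
  if (any(mu <= 0)) stop("poisson_loglik: all means must be strictly positive")
  sum(y * log(mu) - mu - lgamma(y + 1))
}

## saturated log-likelihood: mu_i = y_i with 0 log 0 = 0
poisson_loglik_sat <- function(y) {
  sum(ifelse(y > 0, y * log(y), 0) - y - lgamma(y + 1))
}

#' Poisson deviance
#'
#' Deviance of a model predicting means `mu` for counts `y`:
#' \eqn{D = 2(\ell_{sat} - \ell(\mu))}, where the saturated model sets
#' \eqn{\mu_i = y_i} (with \eqn{0\log 0 \equiv 0}).
#'
#' @inheritParams poisson_loglik
#' @return scalar deviance, nonnegative.
#' @export
poisson_deviance <- function(y, mu) {
  2 * (poisson_loglik_sat(y) - poisson_loglik(y, mu))
}

#' Fraction of deviance explained
#'
#' The Poisson generalization of R-squared: \eqn{R^2 = 1 - D_{model}/D_{null}},
#' where both deviances are evaluated on the same counts (typically held-out
#' cross-validation folds, aggregated by summing deviances over folds).
#'
#' @param y_test counts the deviances are evaluated on.
#' @param mu_model model-predicted means.
#' @param mu_null null (intercept-only) means.
#' @return scalar R-squared (at most 1; negative when the model is worse than
#'   the null model). `NA` with a warning when the null deviance is zero.
#' @export
deviance_explained <- function(y_test, mu_model, mu_null) {
  d_model <- poisson_deviance(y_test, mu_model)
  d_null <- poisson_deviance(y_test, mu_null)
  if (d_null <= 0) {
    warning("null deviance is zero; fraction of deviance explained undefined")
    return(NA_real_)
  }
  1 - d_model / d_null
}

## Elastic-net penalized Poisson objective of a fit, matching the glmnet
## parameterization: -loglik/n + lambda * (alpha |beta|_1 + (1-alpha)|beta|_2^2 / 2),
## with the log y! term dropped (constant in the parameters).
enet_objective <- function(X, y, beta, beta0, lambda, alpha) {
  eta <- as.numeric(X %*% beta) + beta0
  n <- length(y)
  nll <- -sum(y * eta - exp(eta)) / n
  nll + lambda * (alpha * sum(abs(beta)) + (1 - alpha) * sum(beta^2) / 2)
}

## KKT (subgradient) residual of an elastic-net Poisson solution.
## Gradient of the smooth part is t(X) %*% (exp(eta) - y) / n; at a stationary
## point it must lie in -lambda * d(penalty). Returns the max violation.
enet_kkt_residual <- function(X, y, beta, beta0, lambda, alpha) {
  n <- length(y)
  eta <- as.numeric(X %*% beta) + beta0
  g <- as.numeric(crossprod(X, exp(eta) - y)) / n + lambda * (1 - alpha) * beta
  active <- beta != 0
  viol_active <- if (any(active)) {
    max(abs(g[active] + lambda * alpha * sign(beta[active])))
  } else 0
  viol_inactive <- if (any(!active)) {
    max(pmax(abs(g[!active]) - lambda * alpha, 0))
  } else 0
  viol_int <- abs(sum(exp(eta) - y) / n)
  max(viol_active, viol_inactive, viol_int)
}

## assign n observations to k cross-validation folds, seeded
make_folds <- function(n, k, seed = NULL) {
  stopifnot(k >= 2, n >= k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}
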