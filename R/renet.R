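## Relaxed elastic-net Poisson regression.
##
## The estimator is a two-stage procedure: (1) a "naive" elastic-net Poisson
## fit selects a predictor support along the lambda1 penalty path; (2) ridge
## regression restricted to that support "relaxes" the coefficients, undoing
## the l1 over-shrinkage. Hyperparameters (alpha, lambda1 path position,
## lambda2) are chosen jointly by k-fold cross-validated deviance, with the
## ridge penalty picked by the largest-penalty-within-1-SE rule. glmnet
## performs the inner penalized path solves; the surrounding procedure,
## cross-validation and goodness-of-fit are implemented here.

## glmnet's Poisson IRLS conditions badly on uncentered predictors;
## centering changes nothing in the elastic-net objective (the unpenalized
## intercept absorbs the shift), so solve on centered columns and shift the
## intercept back.
center_x <- function(X) {
  cm <- colMeans(X)
  list(x = sweep(X, 2, cm), cm = cm)
}

DEFAULT_ALPHAS <- c(0.001, 0.25, 0.5, 0.75, 0.999)

#' Elastic-net Poisson solution path
#'
#' Computes the penalized Poisson regression path for a fixed elastic-net
#' mixing parameter over 100 log-spaced penalties from the smallest penalty
#' giving an all-zero coefficient vector down to 1e-3 times it.
#'
#' @param X standardized predictor matrix (n bouts by p predictors).
#' @param y nonnegative integer response counts.
#' @param alpha elastic-net mixing parameter in `[0, 1]` (1 = lasso).
#' @param nlambda number of penalties along the path.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest.
#' @return list with `lambda` (descending), `beta` (p x nlambda), `beta0`
#'   (length nlambda) and the underlying `glmnet` fit.
#' @export
fit_enet_path <- function(X, y, alpha, nlambda = 100, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  check_counts(y)
  cx <- center_x(X)
  sx <- glmnet_safe_x(cx$x)
  ## glmnet truncates auto-generated paths once the deviance saturates;
  ## probe lambda_max first, then request the full log-spaced sequence
  probe <- glmnet::glmnet(sx$x, y, family = "poisson", alpha = alpha,
                          nlambda = 3, lambda.min.ratio = 0.9,
                          standardize = FALSE, thresh = 1e-6)
  lam <- exp(seq(log(probe$lambda[1]),
                 log(probe$lambda[1] * lambda_min_ratio),
                 length.out = nlambda))
  fit <- glmnet::glmnet(sx$x, y, family = "poisson", alpha = alpha,
                        lambda = lam, standardize = FALSE, thresh = 1e-8)
  beta <- as.matrix(fit$beta)
  if (sx$pad) beta <- beta[-nrow(beta), , drop = FALSE]
  beta[abs(beta) < 1e-12] <- 0  # numerical dust is not support
  beta0 <- as.numeric(fit$a0) - as.numeric(crossprod(cx$cm, beta))
  list(lambda = fit$lambda, beta = beta, beta0 = beta0,
       alpha = alpha, glmnet_fit = fit)
}

check_counts <- function(y) {
  stopifnot(length(y) > 1, all(is.finite(y)), all(y >= 0))
  if (any(abs(y - round(y)) > 1e-8)) {
    stop("response must contain nonnegative integer spike counts; ",
         "round inferred counts before fitting")
  }
}

## indices of the 10 equally spaced positions along an nlambda-point path
path_positions <- function(nlambda = 100, npos = 10) {
  unique(round(seq(1, nlambda, length.out = npos)))
}

## glmnet refuses single-column x; pad with an all-zero dummy column
glmnet_safe_x <- function(X) {
  if (ncol(X) >= 2) return(list(x = X, pad = FALSE))
  list(x = cbind(X, 0), pad = TRUE)
}

## ridge CV on a restricted predictor set; returns lambda chosen by the
## largest-penalty-within-1-SE rule and its cross-validated mean deviance
ridge_relax_cv <- function(Xm, y, foldid, nlambda = 40) {
  sx <- glmnet_safe_x(center_x(Xm)$x)
  cv <- glmnet::cv.glmnet(sx$x, y, family = "poisson", alpha = 0,
                          foldid = foldid, nlambda = nlambda,
                          standardize = FALSE, type.measure = "deviance",
                          thresh = 1e-6)
  i <- match(cv$lambda.1se, cv$lambda)
  list(lambda2 = cv$lambda.1se, cvm = cv$cvm[i], cvfit = cv)
}

## cross-validated mean deviance of the intercept-only model
null_cv_deviance <- function(y, foldid) {
  dev <- 0
  for (k in sort(unique(foldid))) {
    test <- foldid == k
    mu <- mean(y[!test])
    dev <- dev + poisson_deviance(y[test], max(mu, 1e-12))
  }
  dev / length(y)
}

## fit the restricted ridge model on full data at a fixed lambda2
ridge_refit <- function(Xm, y, lambda2) {
  cx <- center_x(as.matrix(Xm))
  sx <- glmnet_safe_x(cx$x)
  lam <- lambda2 * 2^(10:0)  # warm-start ladder down to lambda2
  fit <- glmnet::glmnet(sx$x, y, family = "poisson", alpha = 0, lambda = lam,
                        standardize = FALSE, thresh = 1e-8, maxit = 5e5)
  b <- as.numeric(stats::coef(fit, s = lambda2, exact = FALSE))
  beta <- b[-1]
  if (sx$pad) beta <- beta[-length(beta)]
  list(beta = beta, beta0 = b[1] - sum(cx$cm * beta))
}

#' Relaxed elastic-net Poisson regression
#'
#' Fits a Poisson GLM of per-bout spike counts on kinematic predictors with
#' relaxed elastic-net regularization. For each mixing parameter in `alpha`,
#' the l1/l2 penalty path is computed and, at 10 equally spaced path
#' positions, the selected support is refit by cross-validated ridge
#' regression (1-SE rule). The (alpha, lambda1, lambda2) combination with the
#' smallest cross-validated deviance is returned, with coefficients exactly
#' zero outside the selected support, together with an honest cross-validated
#' fraction of deviance explained (each fold reselects the support on its
#' training data at the chosen hyperparameters).
#'
#' @param X standardized predictor matrix, one row per bout.
#' @param y nonnegative integer spike counts per bout.
#' @param alpha vector of elastic-net mixing parameters to search.
#' @param relax if `FALSE`, skip the ridge relaxation stage and return the
#'   best naive elastic-net model (alpha and lambda by cross-validation).
#' @param nfolds number of cross-validation folds.
#' @param foldid optional explicit fold assignment (overrides `nfolds`).
#' @param seed seed for the fold permutation.
#' @param keep_data keep `X` and `y` in the returned object (needed by
#'   `residuals()`).
#' @param r2_method how the cross-validated fraction of deviance explained
#'   is computed: `"cv_min"` (default) uses the cross-validated deviance of
#'   the selected model, as produced by the selection procedure itself;
#'   `"refit"` re-runs the whole two-stage procedure inside each fold
#'   (support reselection included) at the chosen hyperparameters.
#' @return an object of class `renet` with elements `beta` (named, length p),
#'   `beta0`, `support` (integer indices), `alpha`, `lambda1`, `lambda2`,
#'   `r2` (cross-validated fraction of deviance explained), `method`,
#'   `basis`, `foldid`, `cv_deviance`.
#' @export
renet <- function(X, y, alpha = DEFAULT_ALPHAS, relax = TRUE, nfolds = 10,
                  foldid = NULL, seed = NULL, keep_data = TRUE,
                  r2_method = c("cv_min", "refit")) {
  r2_method <- match.arg(r2_method)
  X <- as.matrix(X)
  check_counts(y)
  y <- round(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (is.null(foldid)) foldid <- make_folds(n, nfolds, seed = seed)
  nfolds <- length(unique(foldid))
  if (nfolds < 3) stop("at least 3 cross-validation folds are required")

  best <- list(cvm = Inf)
  null_cvm <- null_cv_deviance(y, foldid)
  ## identical supports recur across path positions and alphas; the ridge
  ## relaxation depends only on the support, so cache it
  relax_cache <- new.env(parent = emptyenv())
  for (a in alpha) {
    path <- fit_enet_path(X, y, alpha = a)
    if (!relax) {
      cv <- glmnet::cv.glmnet(center_x(X)$x, y, family = "poisson",
                              alpha = a,
                              foldid = foldid, lambda = path$lambda,
                              standardize = FALSE, type.measure = "deviance",
                              thresh = 1e-6)
      ## 1-SE rule, the same penalty-selection convention as the ridge
      ## relaxation stage
      i <- match(cv$lambda.1se, cv$lambda)
      if (cv$cvm[i] < best$cvm) {
        b <- as.matrix(path$beta)[, match(cv$lambda[i], path$lambda)]
        best <- list(cvm = cv$cvm[i], alpha = a, lambda1 = cv$lambda[i],
                     lambda2 = NA_real_, beta = b,
                     beta0 = path$beta0[match(cv$lambda[i], path$lambda)],
                     support = which(b != 0))
      }
      next
    }
    pos <- path_positions(length(path$lambda))
    for (j in pos) {
      support <- which(path$beta[, j] != 0)
      if (length(support) == 0) {
        cvm <- null_cvm
        if (cvm < best$cvm) {
          best <- list(cvm = cvm, alpha = a, lambda1 = path$lambda[j],
                       lambda2 = NA_real_, beta = numeric(p),
                       beta0 = log(max(mean(y), 1e-12)), support = integer(0))
        }
        next
      }
      key <- paste(support, collapse = ",")
      rr <- relax_cache[[key]]
      if (is.null(rr)) {
        rr <- ridge_relax_cv(X[, support, drop = FALSE], y, foldid)
        relax_cache[[key]] <- rr
      }
      if (rr$cvm < best$cvm) {
        ref <- ridge_refit(X[, support, drop = FALSE], y, rr$lambda2)
        beta <- numeric(p)
        beta[support] <- ref$beta
        best <- list(cvm = rr$cvm, alpha = a, lambda1 = path$lambda[j],
                     lambda2 = rr$lambda2, beta = beta, beta0 = ref$beta0,
                     support = support)
      }
    }
  }

  method <- if (relax) "relaxed" else "naive"
  r2 <- if (r2_method == "cv_min") {
    if (null_cvm <= 0) NA_real_ else 1 - best$cvm / null_cvm
  } else {
    cv_r2_renet(X, y, foldid, best$alpha, best$lambda1, best$lambda2,
                method)
  }
  names(best$beta) <- colnames(X)
  out <- list(beta = best$beta, beta0 = unname(best$beta0),
              support = best$support, alpha = best$alpha,
              lambda1 = best$lambda1, lambda2 = best$lambda2,
              r2 = r2, cv_deviance = best$cvm, method = method,
              basis = "kin", foldid = foldid, nobs = n,
              call = match.call())
  if (keep_data) { out$x <- X; out$y <- y }
  class(out) <- "renet"
  out
}

#' Compare relaxed, naive and ridge fits on one neuron
#'
#' Runs the relaxed elastic net, the naive elastic net and ridge regression
#' with shared cross-validation folds and shared lambda1 paths, and returns
#' the three cross-validated fractions of deviance explained. This is the
#' per-neuron unit of the relaxation-benefit comparison.
#'
#' @inheritParams renet
#' @return named numeric vector `c(relaxed, naive, ridge)`.
#' @export
compare_encoding_methods <- function(X, y, alpha = DEFAULT_ALPHAS,
                                     nfolds = 10, foldid = NULL,
                                     seed = NULL) {
  X <- as.matrix(X)
  check_counts(y)
  y <- round(y)
  if (is.null(foldid)) foldid <- make_folds(length(y), nfolds, seed = seed)
  null_cvm <- null_cv_deviance(y, foldid)
  cxx <- center_x(X)$x
  best_rel <- Inf; best_nai <- Inf
  relax_cache <- new.env(parent = emptyenv())
  for (a in alpha) {
    path <- fit_enet_path(X, y, alpha = a)
    cv <- glmnet::cv.glmnet(cxx, y, family = "poisson", alpha = a,
                            foldid = foldid, lambda = path$lambda,
                            standardize = FALSE, type.measure = "deviance",
                            thresh = 1e-6)
    i <- match(cv$lambda.1se, cv$lambda)
    best_nai <- min(best_nai, cv$cvm[i])
    for (j in path_positions(length(path$lambda))) {
      support <- which(path$beta[, j] != 0)
      if (length(support) == 0) {
        best_rel <- min(best_rel, null_cvm)
        next
      }
      key <- paste(support, collapse = ",")
      rr <- relax_cache[[key]]
      if (is.null(rr)) {
        rr <- ridge_relax_cv(X[, support, drop = FALSE], y, foldid)
        relax_cache[[key]] <- rr
      }
      best_rel <- min(best_rel, rr$cvm)
    }
  }
  cv0 <- glmnet::cv.glmnet(cxx, y, family = "poisson", alpha = 0,
                           foldid = foldid, nlambda = 100,
                           lambda.min.ratio = 1e-4, standardize = FALSE,
                           type.measure = "deviance", thresh = 1e-6)
  ridge_cvm <- cv0$cvm[match(cv0$lambda.1se, cv0$lambda)]
  c(relaxed = 1 - best_rel / null_cvm,
    naive = 1 - best_nai / null_cvm,
    ridge = 1 - ridge_cvm / null_cvm)
}

#' Cross-validated ridge Poisson regression
#'
#' The relaxed procedure constrained to `alpha = 0` and a single stage: a
#' ridge path with the penalty chosen by the 1-SE rule on cross-validated
#' deviance.
#'
#' @inheritParams renet
#' @return an object of class `renet` with `method = "ridge"`.
#' @export
fit_ridge <- function(X, y, nfolds = 10, foldid = NULL, seed = NULL,
                      keep_data = TRUE, r2_method = c("cv_min", "refit")) {
  r2_method <- match.arg(r2_method)
  X <- as.matrix(X)
  check_counts(y)
  y <- round(y)
  n <- nrow(X)
  if (is.null(foldid)) foldid <- make_folds(n, nfolds, seed = seed)
  cx <- center_x(X)
  cv <- glmnet::cv.glmnet(cx$x, y, family = "poisson", alpha = 0,
                          foldid = foldid, nlambda = 100,
                          lambda.min.ratio = 1e-4,
                          standardize = FALSE, type.measure = "deviance",
                          thresh = 1e-6)
  ## 1-SE rule, consistent with the other fitting routes
  i <- match(cv$lambda.1se, cv$lambda)
  b <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda.1se))
  beta <- b[-1]; names(beta) <- colnames(X)
  b[1] <- b[1] - sum(cx$cm * beta)
  r2 <- if (r2_method == "cv_min") {
    ncvm <- null_cv_deviance(y, foldid)
    if (ncvm <= 0) NA_real_ else 1 - cv$cvm[i] / ncvm
  } else {
    cv_r2_renet(X, y, foldid, alpha = 0, lambda1 = cv$lambda.1se,
                lambda2 = NA_real_, method = "ridge")
  }
  out <- list(beta = beta, beta0 = b[1], support = which(beta != 0),
              alpha = 0, lambda1 = cv$lambda.1se, lambda2 = NA_real_,
              r2 = r2, cv_deviance = cv$cvm[i], method = "ridge",
              basis = "kin", foldid = foldid, nobs = n, call = match.call())
  if (keep_data) { out$x <- X; out$y <- y }
  class(out) <- "renet"
  out
}

## honest cross-validated fraction of deviance explained at fixed
## hyperparameters: every fold refits (including support reselection for the
## relaxed method) on its training data only
cv_r2_renet <- function(X, y, foldid, alpha, lambda1, lambda2, method) {
  d_model <- 0; d_null <- 0
  for (k in sort(unique(foldid))) {
    test <- foldid == k
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    mu_null <- max(mean(ytr), 1e-12)
    mu <- tryCatch({
      fit <- refit_at(Xtr, ytr, alpha, lambda1, lambda2, method)
      eta <- as.numeric(X[test, , drop = FALSE] %*% fit$beta) + fit$beta0
      exp(pmin(eta, 30))
    }, error = function(e) rep(mu_null, sum(test)))
    d_model <- d_model + poisson_deviance(y[test], pmax(mu, 1e-12))
    d_null <- d_null + poisson_deviance(y[test], mu_null)
  }
  if (d_null <= 0) return(NA_real_)
  1 - d_model / d_null
}

refit_at <- function(X, y, alpha, lambda1, lambda2, method) {
  if (method == "ridge") {
    return(ridge_refit(X, y, lambda1))
  }
  cx <- center_x(as.matrix(X))
  path <- glmnet::glmnet(cx$x, y, family = "poisson", alpha = alpha,
                         nlambda = 100, lambda.min.ratio = 1e-3,
                         standardize = FALSE, thresh = 1e-8)
  b <- as.numeric(stats::coef(path, s = lambda1, exact = FALSE))
  beta <- b[-1]; beta0 <- b[1] - sum(cx$cm * beta)
  if (method == "naive" || is.na(lambda2)) {
    if (method == "relaxed" && all(beta == 0)) {
      return(list(beta = beta, beta0 = log(max(mean(y), 1e-12))))
    }
    return(list(beta = beta, beta0 = beta0))
  }
  support <- which(beta != 0)
  if (length(support) == 0) {
    return(list(beta = numeric(ncol(X)), beta0 = log(max(mean(y), 1e-12))))
  }
  ref <- ridge_refit(X[, support, drop = FALSE], y, lambda2)
  out <- numeric(ncol(X)); out[support] <- ref$beta
  list(beta = out, beta0 = ref$beta0)
}

#' Fit in both the kinematic and SVD bases and keep the better model
#'
#' Fits the relaxed elastic net on the raw predictor matrix and on its
#' rotation into the right-singular-vector basis, maps the SVD-basis
#' coefficients back to the kinematic basis, and returns the fit with the
#' higher cross-validated fraction of deviance explained.
#'
#' @inheritParams renet
#' @param basis an `svd_basis` object for `X` (computed if missing).
#' @return a `renet` object with an extra `basis` tag (`"kin"` or `"svd"`);
#'   SVD-basis fits carry the rotated coefficients in `gamma_svd` and the
#'   back-mapped coefficients in `beta`.
#' @export
fit_best_basis <- function(X, y, basis = NULL, alpha = DEFAULT_ALPHAS,
                           nfolds = 10, foldid = NULL, seed = NULL) {
  X <- as.matrix(X)
  if (is.null(basis)) basis <- svd_basis(X)
  if (is.null(foldid)) foldid <- make_folds(nrow(X), nfolds, seed = seed)
  fit_kin <- renet(X, y, alpha = alpha, foldid = foldid, keep_data = FALSE)
  fit_svd <- renet(basis$X_svd, y, alpha = alpha, foldid = foldid,
                   keep_data = FALSE)
  if (is.na(fit_svd$r2) || (!is.na(fit_kin$r2) && fit_kin$r2 >= fit_svd$r2)) {
    fit_kin$basis <- "kin"
    return(fit_kin)
  }
  fit_svd$gamma_svd <- fit_svd$beta
  fit_svd$beta <- map_coefficients(basis$V, fit_svd$beta)
  names(fit_svd$beta) <- colnames(X)
  fit_svd$basis <- "svd"
  fit_svd
}

## ---- S3 methods ----------------------------------------------------------

#' @export
print.renet <- function(x, ...) {
  cat(sprintf("%s elastic-net Poisson GLM (%s basis)\n", x$method, x$basis))
  cat(sprintf("  n = %d bouts, p = %d predictors, support size = %d\n",
              x$nobs, length(x$beta), length(x$support)))
  cat(sprintf("  alpha = %g, lambda1 = %.4g, lambda2 = %.4g\n",
              x$alpha, x$lambda1, x$lambda2))
  cat(sprintf("  cross-validated fraction of deviance explained = %.3f\n",
              x$r2))
  invisible(x)
}

#' @export
summary.renet <- function(object, ...) {
  sup <- object$support
  nm <- names(object$beta)
  tab <- data.frame(predictor = if (is.null(nm)) as.character(sup) else nm[sup],
                    beta = unname(object$beta[sup]))
  tab <- tab[order(-abs(tab$beta)), , drop = FALSE]
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.renet"
  out
}

#' @export
print.summary.renet <- function(x, ...) {
  print(x$fit)
  cat("\nNonzero coefficients (by magnitude):\n")
  print(x$coef_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.renet <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}

#' Predict method for relaxed elastic-net Poisson fits
#'
#' @param object a `renet` fit.
#' @param newx predictor matrix in the basis the model was fit in (for SVD
#'   fits, either the rotated matrix or the raw matrix; raw input is detected
#'   by column count and works through the back-mapped coefficients).
#' @param type `"response"` for expected spike counts, `"link"` for the
#'   linear predictor.
#' @param ... unused.
#' @export
predict.renet <- function(object, newx, type = c("response", "link"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  beta <- if (!is.null(object$gamma_svd) &&
              ncol(newx) == length(object$gamma_svd) &&
              !is.null(colnames(newx)) &&
              all(startsWith(colnames(newx), "svd"))) {
    object$gamma_svd
  } else object$beta
  eta <- as.numeric(newx %*% beta) + object$beta0
  if (type == "link") eta else exp(eta)
}

#' @export
residuals.renet <- function(object, type = c("deviance", "pearson",
                                             "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$x)) stop("fit was created with keep_data = FALSE")
  mu <- predict(object, object$x)
  y <- object$y
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = {
           d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' @export
simulate.renet <- function(object, nsim = 1, seed = NULL, newx = NULL, ...) {
  if (is.null(newx)) {
    if (is.null(object$x)) stop("supply newx or fit with keep_data = TRUE")
    newx <- object$x
  }
  mu <- predict(object, newx)
  with_seed(seed, {
    out <- replicate(nsim, stats::rpois(length(mu), mu))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}

#' @export
plot.renet <- function(x, ...) {
  graphics::barplot(x$beta, las = 2, cex.names = 0.5,
                    ylab = "coefficient",
                    main = sprintf("%s fit (%s basis), R2 = %.2f",
                                   x$method, x$basis, x$r2), ...)
  invisible(x)
}
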