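## Population decoding of swim type and kinematics from simulated Poisson
## spiking, pooled at single-cell, anatomical-label or functional-archetype
## resolution, with sparse (grouped LASSO) linear decoders.

#' Assemble a virtual neuron population
#'
#' Stratified sampling without replacement per anatomical label; labels with
#' fewer neurons than requested are sampled with replacement (with a
#' warning).
#'
#' @param anatomical_labels per-neuron anatomical tags of the source pool.
#' @param type_counts named integer vector of per-label counts (defaults to
#'   proportional allocation totaling `total`).
#' @param total population size when `type_counts` is `NULL`.
#' @param seed RNG seed.
#' @return integer indices into the source pool.
#' @export
assemble_population <- function(anatomical_labels, type_counts = NULL,
                                total = 288, seed = NULL) {
  labs <- sort(unique(anatomical_labels))
  if (is.null(type_counts)) {
    avail <- table(anatomical_labels)[labs]
    raw <- as.numeric(avail) / sum(avail) * total
    cnt <- floor(raw)
    rem <- total - sum(cnt)
    if (rem > 0) {
      up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[up] <- cnt[up] + 1
    }
    type_counts <- stats::setNames(as.integer(cnt), labs)
  }
  with_seed(seed, {
    idx <- integer(0)
    for (lb in names(type_counts)) {
      pool <- which(anatomical_labels == lb)
      k <- type_counts[[lb]]
      if (k == 0) next
      if (length(pool) == 0) stop("no neurons with label ", lb)
      if (length(pool) >= k) {
        idx <- c(idx, sample(pool, k))
      } else {
        warning(sprintf("label %s short (%d < %d); sampling with replacement",
                        lb, length(pool), k))
        idx <- c(idx, sample(pool, k, replace = TRUE))
      }
    }
    idx
  })
}

#' Emit Poisson spikes from model-predicted rates
#'
#' @param mu rate matrix (bouts x neurons).
#' @param seed RNG seed.
#' @return integer count matrix of the same shape.
#' @export
emit_decode_spikes <- function(mu, seed = NULL) {
  mu <- as.matrix(mu)
  if (any(!is.finite(mu)) || any(mu < 0)) stop("rates must be finite and >= 0")
  if (any(log(pmax(mu, 1)) > 30)) stop("rate overflow in decode simulation")
  with_seed(seed, {
    Y <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    storage.mode(Y) <- "integer"
    Y
  })
}

#' Pool a spike matrix by neuron grouping
#'
#' @param spike_matrix bouts x neurons counts.
#' @param grouping `"single"` (identity pooling) or a per-neuron label
#'   vector; pooled columns are within-group means. Empty groups are
#'   dropped.
#' @return pooled matrix (bouts x groups).
#' @export
pool_predictors <- function(spike_matrix, grouping = "single") {
  spike_matrix <- as.matrix(spike_matrix)
  if (identical(grouping, "single")) {
    colnames(spike_matrix) <- paste0("cell", seq_len(ncol(spike_matrix)))
    return(spike_matrix)
  }
  stopifnot(length(grouping) == ncol(spike_matrix))
  groups <- sort(unique(grouping))
  out <- vapply(groups, function(g) {
    rowMeans(spike_matrix[, grouping == g, drop = FALSE])
  }, numeric(nrow(spike_matrix)))
  out <- matrix(out, nrow = nrow(spike_matrix),
                dimnames = list(NULL, as.character(groups)))
  out
}

## number of predictors with any nonzero coefficient at each lambda,
## for (multi-response) glmnet fits
active_predictors_path <- function(glmnet_fit) {
  b <- glmnet_fit$beta
  if (!is.list(b)) return(colSums(b != 0))
  any_nz <- Reduce("|", lapply(b, function(m) as.matrix(m != 0)))
  colSums(any_nz)
}

#' Multinomial grouped-LASSO bout-type decoder
#'
#' l1-penalized multinomial logistic regression with the grouped penalty (a
#' predictor is active for all classes or none), ten-fold cross-validated.
#' The confusion matrix is built from prevalidated (held-out) class
#' predictions at the CV-optimal penalty, and the cross-validated
#' multinomial deviance is reported as a function of the number of active
#' predictors.
#'
#' @param pooled pooled predictor matrix (bouts x channels).
#' @param labels bout-type label per bout.
#' @param nfolds CV folds.
#' @param seed fold seed.
#' @return list: `confusion`, `accuracy`, `df_path`, `cv_error_path`,
#'   `lambda`, `df_opt`, `cvfit`.
#' @export
decode_bout_type <- function(pooled, labels, nfolds = 10, seed = NULL,
                             nlambda = 50, thresh = 1e-5) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 bout-type labels")
  foldid <- make_folds(nrow(pooled), nfolds, seed = seed)
  cv <- glmnet::cv.glmnet(as.matrix(pooled), labels, family = "multinomial",
                          type.multinomial = "grouped", alpha = 1,
                          foldid = foldid, type.measure = "deviance",
                          keep = TRUE, standardize = TRUE,
                          nlambda = nlambda, thresh = thresh)
  i <- match(cv$lambda.min, cv$lambda)
  pre <- cv$fit.preval[, , i]  # held-out class scores
  pred <- factor(levels(labels)[apply(pre, 1, which.max)],
                 levels = levels(labels))
  confusion <- table(truth = labels, predicted = pred)
  df_path <- active_predictors_path(cv$glmnet.fit)[seq_along(cv$lambda)]
  list(confusion = confusion,
       accuracy = mean(pred == labels),
       df_path = df_path,
       cv_error_path = cv$cvm,
       lambda = cv$lambda,
       df_opt = df_path[i],
       cvfit = cv)
}

#' Multi-response grouped-LASSO kinematic decoder
#'
#' l1-penalized multi-response linear regression (glmnet `mgaussian`, whose
#' penalty groups each predictor's coefficients across responses), with
#' per-target cross-validated R-squared from prevalidated predictions and
#' cross-validated MSE as a function of the number of active predictors.
#'
#' @param pooled pooled predictor matrix.
#' @param targets standardized kinematic target matrix (bouts x targets).
#' @param nfolds CV folds.
#' @param seed fold seed.
#' @return list: `r2` (per target), `df_path`, `cv_error_path`, `lambda`,
#'   `df_opt`, `cvfit`.
#' @export
decode_kinematics <- function(pooled, targets, nfolds = 10, seed = NULL,
                              nlambda = 50, thresh = 1e-5) {
  targets <- as.matrix(targets)
  const <- apply(targets, 2, stats::sd) < 1e-12
  if (any(const)) {
    warning("constant decoding target(s) dropped: ",
            paste(colnames(targets)[const], collapse = ", "))
    targets <- targets[, !const, drop = FALSE]
  }
  foldid <- make_folds(nrow(pooled), nfolds, seed = seed)
  cv <- glmnet::cv.glmnet(as.matrix(pooled), targets, family = "mgaussian",
                          alpha = 1, foldid = foldid, type.measure = "mse",
                          keep = TRUE, standardize = TRUE,
                          nlambda = nlambda, thresh = thresh)
  i <- match(cv$lambda.min, cv$lambda)
  pre <- cv$fit.preval[, , i]
  r2 <- vapply(seq_len(ncol(targets)), function(j) {
    1 - mean((targets[, j] - pre[, j])^2) / stats::var(targets[, j])
  }, numeric(1))
  names(r2) <- colnames(targets)
  df_path <- active_predictors_path(cv$glmnet.fit)[seq_along(cv$lambda)]
  list(r2 = r2,
       df_path = df_path,
       cv_error_path = cv$cvm,
       lambda = cv$lambda,
       df_opt = df_path[i],
       cvfit = cv)
}

#' Best cross-validated error using at most `max_df` predictors
#'
#' @param decode_result result of [decode_bout_type()] or
#'   [decode_kinematics()].
#' @param max_df predictor budget.
#' @return minimum CV error over path points with `df <= max_df` (`Inf` if
#'   none).
#' @export
cv_error_at_df <- function(decode_result, max_df) {
  ok <- decode_result$df_path <= max_df
  if (!any(ok)) return(Inf)
  min(decode_result$cv_error_path[ok])
}

#' Default kinematic decoding target panel
#'
#' A 20-target panel spanning vigor, frequency, per-half-beat tail angles
#' and velocities, turning/asymmetry summaries and duration, used for
#' desk-scale kinematic decoding.
#'
#' @return character vector of feature names.
#' @export
decode_target_panel <- function() {
  c("vigmax", "vig120", "mean_TBF", "max_TBF",
    paste0("theta_", 1:4, "_s11"), paste0("vel_", 1:4, "_s11"),
    "intcum60ms", "morphAI", "morphAI2", "max_angl", "max_vel",
    "duration", "period_1")
}

#' Run the full decoding suite
#'
#' For each iteration: assemble a virtual population, sample bouts evenly
#' over the 14 bout-type labels, emit Poisson spikes from model-predicted
#' rates, pool at single-cell / anatomical / archetype resolution, and
#' train both decoders. Metrics are aggregated as mean and SEM across
#' iterations.
#'
#' @param X predictor matrix over all bouts (bouts x 225).
#' @param bout_labels bout-type label per bout.
#' @param beta p x n_neurons coefficient matrix of the neurons' (best)
#'   models.
#' @param beta0 per-neuron intercepts.
#' @param archetype_labels,anatomical_labels per-neuron groupings.
#' @param kin_targets matrix of kinematic decoding targets per bout
#'   (standardized within each iteration's bout sample).
#' @param n_iter iterations.
#' @param n_cells population size per iteration.
#' @param n_bouts bout sample size per iteration.
#' @param nfolds CV folds.
#' @param seed master seed.
#' @return list of class `decode_suite`: per-grouping aggregates
#'   (`accuracy`, `kin_r2`, `df_opt`, curves) and the per-iteration
#'   results.
#' @export
run_decoding_suite <- function(X, bout_labels, beta, beta0,
                               archetype_labels, anatomical_labels,
                               kin_targets, n_iter = 10, n_cells = 288,
                               n_bouts = 700, nfolds = 10, seed = 1) {
  X <- as.matrix(X)
  n_all <- nrow(X)
  labels <- as.character(bout_labels)
  kin_targets <- as.matrix(kin_targets)
  iters <- vector("list", n_iter)
  groupings <- c("single", "anatomical", "archetype")
  for (it in seq_len(n_iter)) {
    s <- derive_seed(seed, it)
    cells <- assemble_population(anatomical_labels, total = n_cells,
                                 seed = derive_seed(s, 1))
    ## even bout sample over labels
    bouts <- with_seed(derive_seed(s, 2), {
      out <- integer(0)
      ulab <- sort(unique(labels))
      quota <- diff(round(seq(0, n_bouts, length.out = length(ulab) + 1)))
      for (li in seq_along(ulab)) {
        pool <- which(labels == ulab[li])
        out <- c(out, sample(pool, min(quota[li], length(pool)),
                             replace = length(pool) < quota[li]))
      }
      out
    })
    eta <- X[bouts, , drop = FALSE] %*% beta[, cells, drop = FALSE]
    eta <- sweep(eta, 2, beta0[cells], "+")
    mu <- exp(pmin(eta, 30))
    spikes <- emit_decode_spikes(mu, seed = derive_seed(s, 3))
    targ <- scale(kin_targets[bouts, , drop = FALSE])
    targ[, !is.finite(colSums(targ))] <- 0
    res <- list()
    for (g in groupings) {
      pooled <- switch(g,
                       single = pool_predictors(spikes, "single"),
                       anatomical = pool_predictors(spikes,
                                                    anatomical_labels[cells]),
                       archetype = pool_predictors(spikes,
                                                   archetype_labels[cells]))
      res[[g]] <- list(
        bout = decode_bout_type(pooled, labels[bouts], nfolds,
                                seed = derive_seed(s, 4)),
        kin = decode_kinematics(pooled, targ, nfolds,
                                seed = derive_seed(s, 5)))
    }
    iters[[it]] <- res
  }
  agg <- lapply(groupings, function(g) {
    acc <- vapply(iters, function(r) r[[g]]$bout$accuracy, numeric(1))
    dfb <- vapply(iters, function(r) r[[g]]$bout$df_opt, numeric(1))
    dfk <- vapply(iters, function(r) r[[g]]$kin$df_opt, numeric(1))
    r2 <- rowMeans(vapply(iters, function(r) r[[g]]$kin$r2,
                          numeric(length(iters[[1]][[g]]$kin$r2))))
    list(accuracy_mean = mean(acc),
         accuracy_sem = stats::sd(acc) / sqrt(n_iter),
         df_bout_mean = mean(dfb), df_kin_mean = mean(dfk),
         kin_r2_mean = r2)
  })
  names(agg) <- groupings
  structure(list(aggregate = agg, iterations = iters, seed = seed),
            class = "decode_suite")
}

#' @export
print.decode_suite <- function(x, ...) {
  cat("decode_suite over", length(x$iterations), "iterations\n")
  for (g in names(x$aggregate)) {
    a <- x$aggregate[[g]]
    cat(sprintf("  %-10s accuracy %.3f +- %.3f, mean df (bout) %.1f\n",
                g, a$accuracy_mean, a$accuracy_sem, a$df_bout_mean))
  }
  invisible(x)
}
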