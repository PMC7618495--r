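## Dense grid-search oracle for the penalized Poisson objective on tiny
## problems. The intercept is profiled out in closed form (stationarity in
## beta0 gives exp(beta0) = sum(y) / sum(exp(X beta))), so the grid runs
## over beta only, with iterative refinement around the incumbent optimum.
grid_oracle_objective <- function(X, y, lambda, alpha, width = 1.5,
                                  n_grid = 21, refine = 3) {
  p <- ncol(X)
  center <- rep(0, p)
  best <- Inf
  for (r in seq_len(refine)) {
    axes <- lapply(seq_len(p), function(j) {
      seq(center[j] - width, center[j] + width, length.out = n_grid)
    })
    grid <- as.matrix(expand.grid(axes))
    eta0 <- X %*% t(grid)
    b0 <- log(sum(y) / colSums(exp(eta0)))
    eta <- sweep(eta0, 2, b0, "+")
    nll <- -colSums(y * eta - exp(eta)) / length(y)
    pen <- lambda * (alpha * rowSums(abs(grid)) +
                       (1 - alpha) * rowSums(grid^2) / 2)
    obj <- nll + pen
    i <- which.min(obj)
    best <- obj[i]
    center <- grid[i, ]
    width <- width * 2.5 / (n_grid - 1)
  }
  best
}

## sparse planted Poisson GLM problem on standardized Gaussian predictors
make_planted_glm <- function(n, p, k_nonzero, beta0, seed,
                             coef_range = c(0.3, 0.7)) {
  withr::with_seed(seed, {
    X <- scale(matrix(rnorm(n * p), n, p))
    colnames(X) <- paste0("x", seq_len(p))
    nz <- sample(p, k_nonzero)
    beta <- numeric(p)
    beta[nz] <- sample(c(-1, 1), k_nonzero, TRUE) *
      runif(k_nonzero, coef_range[1], coef_range[2])
    y <- rpois(n, exp(drop(X %*% beta) + beta0))
    list(X = X, y = y, beta = beta, nonzero = sort(nz))
  })
}
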