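#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers never observe a side effect on the global
#' stream. All stochastic operations in the package route their `seed`
#' arguments through this helper.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic arithmetic scheme mapping (master seed, stream index) to a
#' 31-bit child seed, so every random draw in a pipeline run traces back to
#' one master seed.
#'
#' @param seed master integer seed.
#' @param stream nonnegative integer stream index.
#' @return integer child seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), is.numeric(stream))
  ((as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 8191 + 1) %%
    2147483647
}

## moving average with edge replication; centred window of odd length k
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- floor(k / 2)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1):(half + n)]
}

## sliding maximum of |x| over a centred window of odd length k
sliding_max_abs <- function(x, k) {
  n <- length(x)
  half <- floor(k / 2)
  ax <- abs(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- max(ax[lo:hi])
  }
  out
}

## Pearson correlation distance between rows of a matrix, as a dist object.
## Constant rows have undefined correlation; callers must remove them first.
correlation_dist <- function(x) {
  x <- as.matrix(x)
  xs <- x - rowMeans(x)
  s <- sqrt(rowSums(xs^2))
  if (any(s == 0)) stop("correlation distance undefined for constant vectors")
  xs <- xs / s
  d <- 1 - tcrossprod(xs)
  stats::as.dist(pmax(d, 0))
}

## correlation distance between a single vector and each row of a matrix
correlation_dist_to <- function(v, m) {
  m <- rbind(m)
  vs <- v - mean(v)
  sv <- sqrt(sum(vs^2))
  ms <- m - rowMeans(m)
  sm <- sqrt(rowSums(ms^2))
  r <- as.numeric(ms %*% vs) / (sm * sv)
  r[!is.finite(r)] <- 0
  1 - r
}
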