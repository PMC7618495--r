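#' Participation ratio of an eigenvalue spectrum
#'
#' Continuous estimate of effective dimensionality,
#' \eqn{d = (\sum_i \lambda_i)^2 / \sum_i \lambda_i^2}. Equals 1 when all
#' variance sits in one eigenvalue and M when variance is spread evenly over
#' M eigenvalues. Eigenvalues below `1e-12` times the largest are truncated
#' to zero first.
#'
#' @param eigenvalues nonnegative eigenvalues of a covariance matrix.
#' @return scalar effective dimensionality.
#' @export
participation_ratio <- function(eigenvalues) {
  lam <- as.numeric(eigenvalues)
  stopifnot(all(is.finite(lam)), all(lam >= -1e-12))
  lam[lam < 1e-12 * max(lam)] <- 0
  if (all(lam == 0)) stop("participation ratio undefined for all-zero spectrum")
  sum(lam)^2 / sum(lam^2)
}

#' Principal component analysis with participation-ratio dimensionality
#'
#' Eigendecomposition of the column covariance (1/(n-1) normalization) of
#' centered data, via [stats::prcomp()].
#'
#' @param x data matrix, rows are observations.
#' @return list of class `kin_pca` with `eigenvalues` (descending), `d`
#'   (participation ratio), `cum_var` (cumulative fraction of variance),
#'   `loadings` (orthonormal columns), `scores`, `center`.
#' @export
kin_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA requires at least 2 rows")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  lam <- pc$sdev^2
  lam[lam < 1e-12 * max(lam)] <- 0
  structure(list(eigenvalues = lam,
                 d = participation_ratio(lam),
                 cum_var = cumsum(lam) / sum(lam),
                 loadings = pc$rotation,
                 scores = pc$x,
                 center = pc$center),
            class = "kin_pca")
}

#' @export
print.kin_pca <- function(x, ...) {
  cat(sprintf("PCA: %d components, participation ratio d = %.2f\n",
              length(x$eigenvalues), x$d))
  k <- min(10, length(x$cum_var))
  cat(sprintf("  cumulative variance (first %d): %s\n", k,
              paste(sprintf("%.2f", x$cum_var[seq_len(k)]), collapse = " ")))
  invisible(x)
}

#' Singular-value-decomposition predictor basis
#'
#' Factors the (uncentered) predictor matrix as \eqn{X = U \Sigma V^\top} and
#' forms the decorrelated rotated predictor matrix
#' \eqn{X_{svd} = X V = U \Sigma}, whose columns are mutually orthogonal.
#'
#' @param X predictor matrix.
#' @return list of class `svd_basis` with `U`, `d` (singular values), `V`,
#'   and `X_svd` (columns named `svd1..svdp`).
#' @export
svd_basis <- function(X) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)))
  s <- svd(X)
  X_svd <- X %*% s$v
  colnames(X_svd) <- paste0("svd", seq_len(ncol(X_svd)))
  structure(list(U = s$u, d = s$d, V = s$v, X_svd = X_svd),
            class = "svd_basis")
}

#' Map SVD-basis coefficients back to the original predictor basis
#'
#' Given coefficients `gamma_svd` of a model fit on `X_svd = X V`, returns
#' `beta_svd = V gamma_svd`, so that `X beta_svd == X_svd gamma_svd`.
#'
#' @param V right singular vectors of the predictor matrix.
#' @param gamma_svd coefficient vector in the rotated basis.
#' @return coefficient vector in the original basis.
#' @export
map_coefficients <- function(V, gamma_svd) {
  V <- as.matrix(V)
  if (ncol(V) != length(gamma_svd)) stop("dimension mismatch: ncol(V) != length(gamma_svd)")
  as.numeric(V %*% gamma_svd)
}
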