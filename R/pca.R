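#' Principal component analysis of a spectra matrix
#'
#' Computed by singular value decomposition of the column-centered matrix,
#' which is numerically safer than an eigendecomposition of the covariance
#' on long spectral grids. Explained variance is reported as a percentage of
#' the total centered variance. Component signs are fixed so that the
#' largest-magnitude loading element of each component is positive.
#'
#' @param X A `spectra_matrix` or numeric matrix (rows = samples).
#' @param n_components Number of components k, 1 <= k <= min(n-1, p).
#' @return A `pca_model`: list with `n_components`, `scores` (n x k),
#'   `loadings` (p x k, orthonormal columns), `explained_variance_pct`
#'   (percent of total over all min(n-1, p) components), `sdev` (all
#'   singular-value-based sds) and `column_means`.
#' @export
fit_pca <- function(X, n_components) {
  M <- as_X(X)
  n <- nrow(M); p <- ncol(M)
  kmax <- min(n - 1L, p)
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be in 1..", kmax)
  mu <- colMeans(M)
  C <- sweep(M, 2L, mu)
  sv <- svd(C)
  # fix sign: largest |loading| element positive, per component
  for (j in seq_len(min(kmax, ncol(sv$v)))) {
    piv <- which.max(abs(sv$v[, j]))
    if (sv$v[piv, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  d2 <- sv$d[seq_len(kmax)]^2
  structure(list(
    n_components = as.integer(n_components),
    scores = sv$u[, seq_len(n_components), drop = FALSE] %*%
      diag(sv$d[seq_len(n_components)], n_components),
    loadings = sv$v[, seq_len(n_components), drop = FALSE],
    explained_variance_pct = 100 * d2 / sum(d2),
    sdev = sv$d[seq_len(kmax)] / sqrt(n - 1),
    column_means = mu
  ), class = "pca_model")
}

#' Project new spectra onto a fitted PCA model
#'
#' @param model A `pca_model`.
#' @param X_new `spectra_matrix` or numeric matrix on the same grid.
#' @return Score matrix (rows x n_components).
#' @export
pca_project <- function(model, X_new) {
  M <- as_X(X_new)
  if (ncol(M) != length(model$column_means))
    stop("grid length ", ncol(M), " does not match the fitted model (",
         length(model$column_means), ")")
  sweep(M, 2L, model$column_means) %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  k <- x$n_components
  cat(sprintf("<pca_model> %d components; cumulative variance %.1f%%\n",
              k, sum(x$explained_variance_pct[seq_len(k)])))
  invisible(x)
}
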