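# Independent oracles used across the suite. These are deliberately written
# from the textbook definitions, not by calling the package's own code paths.

# Textbook two-block iterative NIPALS for a single response, with prediction
# of new samples by sequential score projection (not via a composed
# regression vector). No sign convention is imposed.
oracle_nipals <- function(X, y, A, tol = 1e-13, maxit = 1000) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  n <- nrow(E); p <- ncol(E)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    u <- f
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- drop(crossprod(E, u)) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tt <- drop(E %*% w)
      qa <- sum(f * tt) / sum(tt^2)
      u <- f * qa / qa^2
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pa <- drop(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pa)
    f <- f - qa * tt
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt; q[a] <- qa
  }
  pred <- function(Xn, ncomp = A) {
    En <- sweep(as.matrix(Xn), 2, xm)
    yh <- rep(ym, nrow(En))
    for (a in seq_len(ncomp)) {
      tn <- drop(En %*% W[, a])
      yh <- yh + q[a] * tn
      En <- En - tcrossprod(tn, P[, a])
    }
    yh
  }
  list(W = W, P = P, T = Tm, q = q, predict = pred)
}

# Minimum-norm least squares prediction via SVD pseudoinverse on centered X.
oracle_lsq_pred <- function(X, y, X_new = X, rtol = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  C <- sweep(X, 2, xm)
  sv <- svd(C)
  pos <- sv$d > rtol * sv$d[1]
  B <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y - ym)) / sv$d[pos])
  drop(sweep(as.matrix(X_new), 2, xm) %*% B) + ym
}

# Brute-force leave-one-out RMSECV with inline pretreatment (SNV or none,
# column centering with training means), predictions from oracle_nipals.
oracle_loo_rmsecv <- function(X, y, a_max, kind = c("none", "snv")) {
  kind <- match.arg(kind)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  pred <- matrix(NA_real_, n, a_max)
  snv1 <- function(M) (M - rowMeans(M)) / apply(M, 1, sd)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]; te <- X[i, , drop = FALSE]
    if (kind == "snv") { tr <- snv1(tr); te <- snv1(te) }
    or <- oracle_nipals(tr, y[-i], a_max)
    for (a in seq_len(a_max)) pred[i, a] <- or$predict(te, a)
  }
  sapply(seq_len(a_max), function(a) sqrt(mean((pred[, a] - y)^2)))
}

# Small random spectra_matrix on an arbitrary descending grid.
rand_sm <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(200, 10, length.out = p)
  X <- matrix(rnorm(n * p), n, p)
  structure(list(sample_ids = paste0("s", seq_len(n)), grid = grid, X = X),
            class = "spectra_matrix")
}

# A tiny low-noise synthetic set reused by several tests.
small_synth <- function(n = 20, seed = 7, noise = 0.005, points = 512) {
  cfg <- generator_config(n_samples = n, grid_points = points,
                          noise_sd = noise, seed = seed)
  synthesize(cfg)
}
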