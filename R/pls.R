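#' Fit a PLS1 calibration model (NIPALS)
#'
#' Sequential NIPALS for a single response: at each step the weight vector is
#' the covariance direction `w = X'y / |X'y|`, scores `t = X w`, loadings
#' `p = X't / t't`, `q = y't / t't`, followed by deflation of X and y. The
#' regression vector is composed as `B = W (P'W)^-1 q`. X and y are centered
#' internally; the centering constants are folded into the intercept, so the
#' model predicts on the same scale it was fit on. Component signs are fixed
#' by making the largest-magnitude element of each weight vector positive.
#'
#' @param X Pretreated predictor matrix (`spectra_matrix` or numeric matrix,
#'   rows = samples). Pretreatment is the caller's contract; see
#'   [pretreat_fit].
#' @param y Numeric response vector (one property), non-constant.
#' @param n_lv Number of latent variables (>= 1, at most the rank of the
#'   centered X).
#' @param property_name Label stored with the model.
#' @param pre Optional fitted `pretreatment` carried for prediction on raw
#'   spectra.
#' @return A `pls_model`: weights `W` (p x a), x-loadings `P`, x-scores `T`,
#'   y-loadings `q`, `regression_vector` (for `n_lv` components), `intercept`,
#'   per-component `t2` (t't), plus centering constants and metadata.
#' @export
fit_pls <- function(X, y, n_lv, property_name = "y", pre = NULL) {
  M <- as_X(X)
  y <- as.numeric(y)
  n <- nrow(M); p <- ncol(M)
  if (length(y) != n) stop("y length ", length(y), " does not match nrow(X)")
  if (any(!is.finite(M)) || any(!is.finite(y))) stop("non-finite input")
  if (stats::sd(y) == 0) stop("y is constant; nothing to calibrate")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L) stop("n_lv must be >= 1")
  if (n < n_lv + 1L) stop("need at least n_lv + 1 samples")

  x_means <- colMeans(M)
  y_mean <- mean(y)
  Xd <- sweep(M, 2L, x_means)
  yd <- y - y_mean
  ss_x0 <- sum(Xd^2)

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv); t2 <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(ss_x0 + 1))
      stop("rank exhausted after ", a - 1L, " components; reduce n_lv")
    w <- w / nw
    piv <- which.max(abs(w))
    if (w[piv] < 0) w <- -w
    tt <- drop(Xd %*% w)
    t2a <- sum(tt^2)
    if (t2a < 1e-20) stop("degenerate score vector at component ", a)
    pa <- drop(crossprod(Xd, tt)) / t2a
    qa <- sum(yd * tt) / t2a
    Xd <- Xd - tcrossprod(tt, pa)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt; q[a] <- qa; t2[a] <- t2a
  }
  B <- pls_regression_vector(W, P, q, n_lv)
  structure(list(
    n_lv = n_lv, W = W, P = P, T = Tm, q = q, t2 = t2,
    regression_vector = B,
    intercept = y_mean - sum(x_means * B),
    x_means = x_means, y_mean = y_mean,
    property_name = property_name, pre = pre
  ), class = "pls_model")
}

# B for the first `a` components: W_a (P_a' W_a)^-1 q_a
pls_regression_vector <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' Predict a property from pretreated spectra
#'
#' @param object A `pls_model`.
#' @param X_new Matrix or `spectra_matrix`, pretreated exactly as the
#'   calibration data (use the stored pretreatment via [pretreat_apply]).
#' @param n_lv Predict with a truncated model (defaults to the fitted count).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, X_new, n_lv = object$n_lv, ...) {
  M <- as_X(X_new)
  if (ncol(M) != length(object$regression_vector))
    stop("grid length ", ncol(M), " does not match the model (",
         length(object$regression_vector), ")")
  if (n_lv == object$n_lv) {
    B <- object$regression_vector
    b0 <- object$intercept
  } else {
    if (n_lv < 1L || n_lv > object$n_lv) stop("n_lv out of fitted range")
    B <- pls_regression_vector(object$W, object$P, object$q, n_lv)
    b0 <- object$y_mean - sum(object$x_means * B)
  }
  drop(M %*% B) + b0
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s: %d latent variables, %d channels\n",
              x$property_name, x$n_lv, length(x$regression_vector)))
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS1 calibration
#'
#' For every left-out sample the whole chain is refit on the remaining n-1
#' spectra — pretreatment parameters (MSC reference, column means) included,
#' so the held-out spectrum never informs its own prediction. RMSECV is
#' reported for 1..a_max latent variables; `chosen_lv` follows the parsimony
#' rule of [select_n_lv] and `r_cv` is the Pearson correlation between the
#' LOO predictions at `chosen_lv` and the reference values.
#'
#' @param X Raw (un-pretreated) `spectra_matrix` or numeric matrix.
#' @param y Response vector.
#' @param a_max Maximum number of latent variables to scan.
#' @param kind Pretreatment kind, as in [pretreat_fit].
#' @param windows Optional [window_set] applied inside each fold.
#' @param parsimony_tol Tolerance for [select_n_lv].
#' @return A `cv_result`: `rmsecv_by_lv`, `r_cv`, `chosen_lv`, and the n x
#'   a_max matrix of LOO `predictions`.
#' @export
loo_cv <- function(X, y, a_max, kind = "none", windows = NULL,
                   parsimony_tol = 0.02) {
  M <- as_X(X)
  y <- as.numeric(y)
  n <- nrow(M)
  if (length(y) != n) stop("y length does not match nrow(X)")
  if (n < a_max + 2L) stop("need n >= a_max + 2 for leave-one-out")
  sm <- if (inherits(X, "spectra_matrix")) X else
    structure(list(sample_ids = paste0("s", seq_len(n)),
                   grid = seq_len(ncol(M)), X = M), class = "spectra_matrix")
  preds <- matrix(NA_real_, n, a_max)
  for (i in seq_len(n)) {
    tr <- sm_rows(sm, setdiff(seq_len(n), i))
    te <- sm_rows(sm, i, allow_single = TRUE)
    ft <- pretreat_fit(tr, kind = kind, windows = windows)
    m <- fit_pls(ft$X, y[-i], n_lv = a_max)
    Xte <- pretreat_apply(te, ft$pre)
    for (a in seq_len(a_max))
      preds[i, a] <- predict(m, Xte, n_lv = a)
  }
  rmsecv <- vapply(seq_len(a_max), function(a) rmse(preds[, a], y), 0)
  chosen <- select_n_lv(rmsecv, parsimony_tol)
  structure(list(rmsecv_by_lv = rmsecv,
                 r_cv = pearson_r(preds[, chosen], y),
                 chosen_lv = chosen,
                 predictions = preds),
            class = "cv_result")
}

#' Choose the number of latent variables from an RMSECV curve
#'
#' Parsimony plateau rule: the smallest component count whose RMSECV is
#' within `parsimony_tol` (relative) of the curve minimum. With few
#' calibration samples the bare argmin chases noise; the plateau rule stops
#' where added components no longer buy real cross-validated accuracy.
#'
#' @param cv A `cv_result` or a numeric RMSECV vector over 1..a_max.
#' @param parsimony_tol Relative tolerance (default 0.02).
#' @return Integer component count.
#' @export
select_n_lv <- function(cv, parsimony_tol = 0.02) {
  r <- if (inherits(cv, "cv_result")) cv$rmsecv_by_lv else as.numeric(cv)
  if (!length(r)) stop("empty RMSECV curve")
  which(r <= min(r) * (1 + parsimony_tol))[1L]
}

#' Variable importance in projection (VIP) scores
#'
#' Standard Wold VIP: `VIP_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )`
#' with `SS_a = q_a^2 t_a't_a`, the y-variance explained by component a, and
#' unit-norm weight vectors. The mean squared VIP equals 1, so channels with
#' VIP > 1 carry above-average predictive weight — the usual screen for
#' selecting informative spectral ranges.
#'
#' @param model A fitted `pls_model`.
#' @return Numeric vector of length p (one score per spectral channel).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ss <- model$q^2 * model$t2
  p <- nrow(model$W)
  sqrt(p * drop(model$W^2 %*% ss) / sum(ss))
}

#' Serialize / restore a PLS calibration model
#'
#' Writes a self-describing plain-text file carrying everything needed to
#' predict new spectra bit-reproducibly: the regression vector, intercept,
#' pretreatment kind and parameters (MSC reference, column means, windows)
#' and the ppm grid. Numbers are stored at full double precision.
#'
#' @param model A `pls_model` fitted with its `pre` attached.
#' @param sink,source File path.
#' @return `read_pls_model` returns a `pls_model` limited to prediction
#'   (components W/P/T are not stored).
#' @export
write_pls_model <- function(model, sink) {
  stopifnot(inherits(model, "pls_model"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  pre <- model$pre
  out <- c("nmrcal-pls-model 1",
           paste0("property ", model$property_name),
           paste0("n_lv ", model$n_lv),
           paste0("intercept ", num(model$intercept)),
           paste0("regression_vector ", num(model$regression_vector)))
  if (!is.null(pre)) {
    out <- c(out,
             paste0("pre_kind ", pre$kind),
             paste0("grid ", num(pre$grid)),
             paste0("column_means ", num(pre$column_means)))
    if (!is.null(pre$msc_reference))
      out <- c(out, paste0("msc_reference ", num(pre$msc_reference)))
    if (!is.null(pre$windows))
      out <- c(out, paste0("windows ", num(as.numeric(t(unclass(pre$windows))))))
  }
  writeLines(out, sink)
  invisible(TRUE)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (!startsWith(lines[1L], "nmrcal-pls-model"))
    stop("'", source, "' is not a serialized PLS model")
  fields <- list()
  for (ln in lines[-1L]) {
    sp <- regexpr(" ", ln)
    fields[[substr(ln, 1L, sp - 1L)]] <- substr(ln, sp + 1L, nchar(ln))
  }
  vec <- function(nm) if (is.null(fields[[nm]])) NULL else
    as.numeric(strsplit(fields[[nm]], " ")[[1L]])
  pre <- NULL
  if (!is.null(fields$pre_kind)) {
    w <- vec("windows")
    pre <- structure(list(kind = fields$pre_kind,
                          windows = if (is.null(w)) NULL else
                            window_set(matrix(w, ncol = 2L, byrow = TRUE)),
                          msc_reference = vec("msc_reference"),
                          column_means = vec("column_means"),
                          grid = vec("grid")),
                     class = "pretreatment")
  }
  B <- vec("regression_vector")
  structure(list(n_lv = as.integer(fields$n_lv),
                 regression_vector = B,
                 intercept = vec("intercept"),
                 property_name = fields$property,
                 pre = pre),
            class = "pls_model")
}

# row subset of a spectra_matrix (internal)
sm_rows <- function(sm, idx, allow_single = FALSE) {
  structure(list(sample_ids = sm$sample_ids[idx], grid = sm$grid,
                 X = sm$X[idx, , drop = FALSE]),
            class = "spectra_matrix")
}
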