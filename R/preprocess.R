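#' Standard normal variate transform
#'
#' Each spectrum (row) is centered to mean zero and scaled to unit sample
#' standard deviation (n-1 denominator). Removes per-sample multiplicative
#' and additive scatter without a reference spectrum.
#'
#' @param X A `spectra_matrix` or numeric matrix (rows = samples).
#' @return Object of the same type with transformed rows.
#' @export
snv_transform <- function(X) {
  M <- as_X(X)
  sds <- apply(M, 1L, stats::sd)
  if (any(sds == 0)) {
    id <- row_id(X, which(sds == 0)[1L])
    stop("constant spectrum (zero variance): sample ", id)
  }
  out <- (M - rowMeans(M)) / sds
  wrap_like(X, out)
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, x = a + b * ref + e, and replaced by (x - a) / b. The reference
#' defaults to the mean spectrum of the input (the calibration set); the
#' fitted reference must be reused to transform validation or unknown
#' spectra so no information leaks from them into the pretreatment.
#'
#' @param X A `spectra_matrix` or numeric matrix (rows = samples).
#' @param reference `"mean"` or a numeric vector of grid length.
#' @return List with `X` (transformed, same type as input) and `reference`
#'   (the spectrum used, for later [msc_apply]).
#' @export
msc_fit <- function(X, reference = "mean") {
  M <- as_X(X)
  if (identical(reference, "mean")) {
    if (nrow(M) < 2L) stop("need >= 2 spectra to fit a mean MSC reference")
    reference <- colMeans(M)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(M))
    stop("MSC reference length ", length(reference),
         " does not match grid length ", ncol(M))
  if (stats::var(reference) == 0) stop("MSC reference has zero variance")
  out <- msc_apply(X, reference)
  list(X = out, reference = reference)
}

#' @rdname msc_fit
#' @export
msc_apply <- function(X, reference) {
  M <- as_X(X)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(M))
    stop("MSC reference length does not match grid length")
  rc <- reference - mean(reference)
  ssr <- sum(rc^2)
  b <- as.numeric(M %*% rc) / ssr              # OLS slope per row
  a <- rowMeans(M) - b * mean(reference)       # OLS intercept per row
  if (any(abs(b) < 1e-12)) {
    id <- row_id(X, which(abs(b) < 1e-12)[1L])
    stop("MSC slope ~ 0 for sample ", id, "; correction undefined")
  }
  wrap_like(X, (M - a) / b)
}

#' Column mean-centering
#'
#' Subtracts calibration column means; the means are returned so that
#' validation or unknown spectra can be centered with the calibration
#' parameters rather than their own.
#'
#' @param X A `spectra_matrix` or numeric matrix.
#' @param means Optional precomputed column means (length p) to apply.
#' @return List with `X` (centered) and `means`.
#' @export
mean_center <- function(X, means = NULL) {
  M <- as_X(X)
  if (is.null(means)) {
    if (nrow(M) < 2L) stop("need >= 2 rows to estimate column means")
    means <- colMeans(M)
  }
  if (length(means) != ncol(M)) stop("means length does not match grid")
  list(X = wrap_like(X, sweep(M, 2L, means)), means = as.numeric(means))
}

#' Define a set of ppm windows
#'
#' Windows are closed `(high_ppm, low_ppm)` intervals on the descending
#' chemical-shift axis; they must not overlap.
#'
#' @param ... Numeric length-2 vectors `c(high, low)`, or a single list of
#'   them, or an n x 2 matrix with columns high, low.
#' @return A `window_set`: n x 2 matrix with columns `high`, `low`.
#' @export
window_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is.numeric(args[[1L]]))
    args <- args[[1L]]
  if (length(args) == 1L && is.matrix(args[[1L]])) {
    w <- args[[1L]]
  } else {
    w <- do.call(rbind, lapply(args, function(p) {
      if (length(p) != 2L) stop("each window must be c(high_ppm, low_ppm)")
      as.numeric(p)
    }))
  }
  if (any(w[, 1L] <= w[, 2L]))
    stop("window high_ppm must exceed low_ppm")
  o <- order(w[, 1L], decreasing = TRUE)
  w <- w[o, , drop = FALSE]
  if (nrow(w) > 1L && any(w[-nrow(w), 2L] < w[-1L, 1L]))
    stop("windows overlap after sorting")
  dimnames(w) <- list(NULL, c("high", "low"))
  structure(w, class = c("window_set", "matrix"))
}

#' Restrict a spectra matrix to ppm windows
#'
#' Grid points falling inside any window are kept (closed intervals), in
#' their original order; all other columns are dropped.
#'
#' @param X A `spectra_matrix`.
#' @param w A [window_set], or anything `window_set()` accepts.
#' @return A `spectra_matrix` on the restricted grid.
#' @export
apply_windows <- function(X, w) {
  stopifnot(inherits(X, "spectra_matrix"))
  if (!inherits(w, "window_set")) w <- window_set(w)
  keep <- window_mask(X$grid, w)
  if (!any(keep)) stop("no grid points fall inside the windows")
  structure(list(sample_ids = X$sample_ids, grid = X$grid[keep],
                 X = X$X[, keep, drop = FALSE]),
            class = "spectra_matrix")
}

window_mask <- function(grid, w) {
  keep <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(w)))
    keep <- keep | (grid <= w[i, 1L] & grid >= w[i, 2L])
  keep
}

#' Fit a pretreatment on calibration spectra
#'
#' Bundles the modeling pretreatment chain: ppm windowing, then one of
#' none / MSC / SNV, then mean-centering — in that order. Parameters with a
#' fit (MSC reference, column means) are learned here and reapplied verbatim
#' by [pretreat_apply] so validation samples never influence them.
#'
#' @param X Calibration `spectra_matrix`.
#' @param kind `"none"`, `"msc"` or `"snv"`.
#' @param windows Optional [window_set]; `NULL` keeps the full grid.
#' @return List with `X` (pretreated calibration matrix) and `pre`
#'   (a `pretreatment` object holding kind, windows, MSC reference, means).
#' @export
pretreat_fit <- function(X, kind = c("none", "msc", "snv"), windows = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(X, "spectra_matrix"))
  if (!is.null(windows)) X <- apply_windows(X, windows)
  ref <- NULL
  if (kind == "msc") {
    f <- msc_fit(X, "mean")
    X <- f$X; ref <- f$reference
  } else if (kind == "snv") {
    X <- snv_transform(X)
  }
  cen <- mean_center(X)
  pre <- structure(list(kind = kind, windows = windows, msc_reference = ref,
                        column_means = cen$means, grid = X$grid),
                   class = "pretreatment")
  list(X = cen$X, pre = pre)
}

#' @rdname pretreat_fit
#' @param pre A fitted `pretreatment`.
#' @export
pretreat_apply <- function(X, pre) {
  stopifnot(inherits(X, "spectra_matrix"), inherits(pre, "pretreatment"))
  if (!is.null(pre$windows)) X <- apply_windows(X, pre$windows)
  if (length(X$grid) != length(pre$grid) ||
      max(abs(X$grid - pre$grid)) > 1e-9)
    stop("spectra grid does not match the pretreatment's fitted grid")
  if (pre$kind == "msc") X <- msc_apply(X, pre$msc_reference)
  else if (pre$kind == "snv") X <- snv_transform(X)
  mean_center(X, means = pre$column_means)$X
}

# --- small internal helpers shared by matrix-or-spectra_matrix functions ---

as_X <- function(X) {
  if (inherits(X, "spectra_matrix")) return(X$X)
  if (is.matrix(X) && is.numeric(X)) return(X)
  stop("expected a spectra_matrix or numeric matrix")
}

wrap_like <- function(X, M) {
  if (inherits(X, "spectra_matrix")) spectra_matrix_like(X, M) else M
}

row_id <- function(X, i) {
  if (inherits(X, "spectra_matrix")) X$sample_ids[i] else paste0("row ", i)
}
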