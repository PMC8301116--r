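#' Kennard-Stone maximin selection
#'
#' Classic coverage design: start from the two mutually most distant points,
#' then repeatedly add the candidate whose nearest selected neighbour is
#' farthest away. Returns indices into the rows of `scores`.
#'
#' @param scores Numeric matrix (rows = samples) — typically PCA scores.
#' @param k Number of points to select (2 <= k <= n).
#' @param candidates Optional subset of row indices to select from.
#' @param preselected Optional indices treated as already selected (count
#'   toward `k`).
#' @return Integer vector of `k` selected row indices.
#' @export
kennard_stone <- function(scores, k, candidates = seq_len(nrow(scores)),
                          preselected = integer()) {
  scores <- as.matrix(scores)
  candidates <- unique(as.integer(candidates))
  preselected <- unique(as.integer(preselected))
  pool <- setdiff(candidates, preselected)
  sel <- preselected
  if (k < length(sel)) stop("k smaller than the preselected set")
  if (k > length(sel) + length(pool)) stop("k exceeds available candidates")
  if (!length(sel)) {
    if (k < 2L) stop("k must be >= 2 when nothing is preselected")
    D <- as.matrix(stats::dist(scores[pool, , drop = FALSE]))
    ij <- which(D == max(D), arr.ind = TRUE)[1L, ]
    sel <- pool[c(ij[1L], ij[2L])]
    pool <- setdiff(pool, sel)
  }
  # min distance from each pool point to the selected set, updated greedily
  mind <- rep(Inf, nrow(scores))
  for (s in sel)
    mind <- pmin(mind, sqrt(rowSums(sweep(scores, 2L, scores[s, ])^2)))
  while (length(sel) < k) {
    nxt <- pool[which.max(mind[pool])]
    sel <- c(sel, nxt)
    pool <- setdiff(pool, nxt)
    mind <- pmin(mind, sqrt(rowSums(sweep(scores, 2L, scores[nxt, ])^2)))
  }
  sel
}

#' Calibration/validation split by bootstrap-stabilized Kennard-Stone in PCA
#' score space
#'
#' The sample set is embedded in a low-dimensional PCA score space; across
#' bootstrap resamples a Kennard-Stone coverage design repeatedly nominates
#' calibration candidates, and the samples nominated most often form the
#' calibration set. Per-component score extremes are forced into calibration
#' so every validation sample is an interpolation, never an extrapolation —
#' the intent behind combining bootstrap resampling with PCA score plots for
#' a representative 25/10 partition.
#'
#' @param X A `spectra_matrix` (or numeric matrix with rownames as ids).
#' @param n_val Number of validation samples (default 10).
#' @param n_boot Bootstrap repetitions (default 200).
#' @param k_pcs Number of PCA components for the score space (default 5).
#' @param seed Integer seed; the split is deterministic given it.
#' @return A `sample_split`: `calibration_ids`, `validation_ids`, `seed`,
#'   `method`, plus the integer index vectors `cal_idx`/`val_idx` in row
#'   order of `X`.
#' @export
pca_coverage_split <- function(X, n_val = 10L, n_boot = 200L, k_pcs = 5L,
                               seed = 1L) {
  M <- as_X(X)
  n <- nrow(M)
  ids <- if (inherits(X, "spectra_matrix")) X$sample_ids
         else rownames(M) %||% as.character(seq_len(n))
  if (n_val >= n) stop("n_val must be smaller than the number of samples")
  n_cal <- n - n_val
  k_pcs <- min(k_pcs, n - 1L)
  sc <- fit_pca(X, k_pcs)$scores
  forced <- unique(as.integer(c(apply(sc, 2L, which.min),
                                apply(sc, 2L, which.max))))
  if (length(forced) > n_cal)
    stop("more per-PC extreme samples (", length(forced),
         ") than calibration slots (", n_cal, ")")
  votes <- integer(n)
  # order-independent RNG: seed per bootstrap replicate, ids sorted for draws
  ord <- order(ids)
  for (b in seq_len(n_boot)) {
    set.seed((as.integer(seed) + b) %% .Machine$integer.max)
    boot <- unique(ord[sample.int(n, n, replace = TRUE)])
    cand <- union(boot, forced)
    k <- min(n_cal, length(cand))
    sel <- kennard_stone(sc, k, candidates = cand,
                         preselected = intersect(forced, cand))
    votes[sel] <- votes[sel] + 1L
  }
  votes[forced] <- votes[forced] + n_boot   # extremes always calibrate
  # deterministic tie-break: votes, then distance from score centroid
  d0 <- sqrt(rowSums(sc^2))
  cal <- order(-votes, -d0, ids)[seq_len(n_cal)]
  cal <- sort(cal)
  val <- setdiff(seq_len(n), cal)
  structure(list(calibration_ids = ids[cal], validation_ids = ids[val],
                 cal_idx = cal, val_idx = val,
                 seed = as.integer(seed),
                 method = "bootstrap-kennard-stone-pca"),
            class = "sample_split")
}

#' Uniform random calibration/validation split
#'
#' Baseline partition: validation samples drawn uniformly without
#' replacement. Deterministic under `seed`.
#'
#' @param ids Character vector of sample ids.
#' @param n_val Number of validation samples.
#' @param seed Integer seed.
#' @return A `sample_split` (same shape as [pca_coverage_split]).
#' @export
random_split <- function(ids, n_val, seed = 1L) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n_val >= n) stop("n_val must be smaller than the number of samples")
  set.seed(as.integer(seed))
  val <- sort(sample.int(n, n_val))
  cal <- setdiff(seq_len(n), val)
  structure(list(calibration_ids = ids[cal], validation_ids = ids[val],
                 cal_idx = cal, val_idx = val,
                 seed = as.integer(seed), method = "random"),
            class = "sample_split")
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf("<sample_split> %s: %d calibration / %d validation (seed %d)\n",
              x$method, length(x$calibration_ids), length(x$validation_ids),
              x$seed))
  invisible(x)
}

#' Save / load a split as a two-column CSV (sample_id, role)
#'
#' @param split A `sample_split`.
#' @param sink,source File path.
#' @param ids Row order to restore index vectors against (for `read_split`).
#' @export
write_split <- function(split, sink) {
  d <- data.frame(
    sample_id = c(split$calibration_ids, split$validation_ids),
    role = rep(c("calibration", "validation"),
               c(length(split$calibration_ids), length(split$validation_ids))))
  utils::write.csv(d, sink, row.names = FALSE)
  invisible(TRUE)
}

#' @rdname write_split
#' @export
read_split <- function(source, ids) {
  d <- utils::read.csv(source, stringsAsFactors = FALSE)
  ids <- as.character(ids)
  if (!setequal(d$sample_id, ids))
    stop("split ids do not match the provided sample ids")
  cal_ids <- d$sample_id[d$role == "calibration"]
  val_ids <- d$sample_id[d$role == "validation"]
  structure(list(calibration_ids = cal_ids, validation_ids = val_ids,
                 cal_idx = sort(match(cal_ids, ids)),
                 val_idx = sort(match(val_ids, ids)),
                 seed = NA_integer_, method = "loaded"),
            class = "sample_split")
}
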