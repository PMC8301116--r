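#' Default per-property modeling configuration
#'
#' One block per property with the pretreatment and latent-variable count
#' used for the final reported models: reducing sugars (MSC, 4 LV, restricted
#' to 220-55 ppm), protein (SNV, 4), fat (SNV, 4), NHCS sum (none, 5),
#' C (none, 5), N (SNV, 4), S (MSC, 5), TP (MSC, 4), ABTS (none, 3) and
#' pH (none, 7). Spectral ranges other than the reducing-sugars window are
#' modeling choices left to configuration; the default keeps the full grid.
#'
#' @param properties Subset of properties to include (default all ten).
#' @return A `run_config`: list with `blocks` (per-property settings),
#'   `split` (method/n_val/n_boot/k_pcs) and `parsimony_tol`.
#' @export
default_run_config <- function(properties = reference_properties()) {
  blk <- function(property, pretreatment, n_lv, windows = NULL)
    list(property = property, pretreatment = pretreatment, n_lv = n_lv,
         windows = windows, a_max = 10L)
  blocks <- list(
    blk("reducing_sugars", "msc", 4L, window_set(c(220, 55))),
    blk("protein", "snv", 4L),
    blk("fat", "snv", 4L),
    blk("nhcs", "none", 5L),
    blk("c", "none", 5L),
    blk("n", "snv", 4L),
    blk("s", "msc", 5L),
    blk("tp", "msc", 4L),
    blk("abts", "none", 3L),
    blk("ph", "none", 7L)
  )
  names(blocks) <- vapply(blocks, `[[`, "", "property")
  blocks <- blocks[intersect(names(blocks), properties)]
  structure(list(blocks = blocks,
                 split = list(method = "pca", n_val = 10L, n_boot = 200L,
                              k_pcs = 5L),
                 parsimony_tol = 0.02),
            class = "run_config")
}

#' Run the full calibration workflow over all configured properties
#'
#' One shared calibration/validation split is used for every property. Per
#' property: ppm windowing, pretreatment fit on the calibration spectra
#' only, PLS1 fit (fixed latent-variable count or leave-one-out "auto"
#' selection), prediction of both sets, and RSEP/R/R_cv reporting. All
#' pretreatment parameters applied to validation spectra are the ones
#' learned on the calibration set, so validation never leaks into fitting.
#'
#' @param spectra A `spectra_matrix`.
#' @param refs A `reference_table`; `sample_id`s must match `spectra`
#'   (same order).
#' @param cfg A `run_config` (default [default_run_config()]).
#' @param split Optional precomputed `sample_split`; otherwise one is built
#'   per `cfg$split` under `seed`.
#' @param seed Integer seed for the split.
#' @return A `calibration_run`: `report` (data.frame, one row per property:
#'   property, pretreatment, n_lv, r, r_cv, rsep_cal_pct, rsep_val_pct,
#'   rmse_cal, rmse_val), `models` (fitted `pls_model`s), `cv` (per-property
#'   `cv_result`s), `split`, `config`.
#' @export
run_calibration <- function(spectra, refs, cfg = default_run_config(),
                            split = NULL, seed = 1L) {
  stopifnot(inherits(spectra, "spectra_matrix"),
            inherits(cfg, "run_config"))
  if (!identical(as.character(spectra$sample_ids),
                 as.character(refs$sample_id)))
    stop("sample ids of spectra and reference table do not align")
  miss <- setdiff(names(cfg$blocks), names(refs))
  if (length(miss))
    stop("reference table lacks configured propert",
         if (length(miss) > 1) "ies: " else "y: ",
         paste(miss, collapse = ", "))
  if (is.null(split)) {
    split <- if (identical(cfg$split$method, "random"))
      random_split(spectra$sample_ids, cfg$split$n_val, seed = seed)
    else
      pca_coverage_split(spectra, n_val = cfg$split$n_val,
                         n_boot = cfg$split$n_boot, k_pcs = cfg$split$k_pcs,
                         seed = seed)
  }
  cal <- sm_rows(spectra, split$cal_idx)
  val <- sm_rows(spectra, split$val_idx)

  rows <- list(); models <- list(); cvs <- list()
  for (b in cfg$blocks) {
    y_cal <- refs[[b$property]][split$cal_idx]
    y_val <- refs[[b$property]][split$val_idx]
    if (stats::sd(y_cal) == 0)
      stop("property '", b$property, "' is constant on the calibration set")
    ft <- pretreat_fit(cal, kind = b$pretreatment, windows = b$windows)
    auto <- identical(b$n_lv, "auto")
    a_scan <- if (auto) b$a_max else as.integer(b$n_lv)
    cv <- loo_cv(cal, y_cal, a_max = a_scan, kind = b$pretreatment,
                 windows = b$windows, parsimony_tol = cfg$parsimony_tol)
    n_lv <- if (auto) cv$chosen_lv else as.integer(b$n_lv)
    m <- fit_pls(ft$X, y_cal, n_lv = n_lv, property_name = b$property,
                 pre = ft$pre)
    pred_cal <- predict(m, ft$X)
    pred_val <- predict(m, pretreat_apply(val, ft$pre))
    rows[[b$property]] <- data.frame(
      property = b$property,
      pretreatment = b$pretreatment,
      n_lv = n_lv,
      r = pearson_r(pred_cal, y_cal),
      r_cv = pearson_r(cv$predictions[, n_lv], y_cal),
      rsep_cal_pct = rsep(pred_cal, y_cal),
      rsep_val_pct = rsep(pred_val, y_val),
      rmse_cal = rmse(pred_cal, y_cal),
      rmse_val = rmse(pred_val, y_val),
      stringsAsFactors = FALSE)
    models[[b$property]] <- m
    cvs[[b$property]] <- cv
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, models = models, cv = cvs,
                 split = split, config = cfg),
            class = "calibration_run")
}

#' @export
print.calibration_run <- function(x, ...) {
  cat(sprintf("<calibration_run> %d properties, %d/%d split\n",
              nrow(x$report), length(x$split$calibration_ids),
              length(x$split$validation_ids)))
  r <- x$report
  r$r <- sprintf("%.3f", r$r); r$r_cv <- sprintf("%.3f", r$r_cv)
  r$rsep_cal_pct <- sprintf("%.2f", r$rsep_cal_pct)
  r$rsep_val_pct <- sprintf("%.2f", r$rsep_val_pct)
  print(r[, c("property", "pretreatment", "n_lv", "r", "r_cv",
              "rsep_cal_pct", "rsep_val_pct")], row.names = FALSE)
  invisible(x)
}

#' Write / read the calibration report CSV
#'
#' Columns follow the summary-table layout: property, pretreatment, number
#' of latent variables, R, R_cv, RSEP for calibration and validation sets.
#' RSEP percentages are written with 2 decimals and correlations with 3, the
#' precision at which such tables are reported; rereading reproduces the
#' written values exactly.
#'
#' @param run A `calibration_run` or its `report` data.frame.
#' @param sink,source File path.
#' @return `read_report` returns the report data.frame.
#' @export
write_report <- function(run, sink) {
  r <- if (inherits(run, "calibration_run")) run$report else run
  out <- data.frame(property = r$property,
                    pretreatment = r$pretreatment,
                    n_lv = r$n_lv,
                    r = sprintf("%.3f", r$r),
                    r_cv = sprintf("%.3f", r$r_cv),
                    rsep_cal_pct = sprintf("%.2f", r$rsep_cal_pct),
                    rsep_val_pct = sprintf("%.2f", r$rsep_val_pct),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  invisible(TRUE)
}

#' @rdname write_report
#' @export
read_report <- function(source) {
  d <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("property", "pretreatment", "n_lv", "r", "r_cv",
            "rsep_cal_pct", "rsep_val_pct")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("report missing column(s): ", paste(miss, collapse = ", "))
  d
}
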