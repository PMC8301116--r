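#' Relative standard error of prediction (RSEP, %)
#'
#' `100 * sqrt( sum((pred - ref)^2) / sum(ref^2) )`. Unit-free: jointly
#' rescaling predictions and reference values leaves it unchanged, which is
#' what makes it comparable across properties measured in different units.
#'
#' @param pred Predicted values.
#' @param ref Reference (assay) values; must not be all zero.
#' @return RSEP as a percentage.
#' @export
rsep <- function(pred, ref) {
  check_pair(pred, ref)
  if (all(ref == 0)) stop("reference values are all zero; RSEP undefined")
  100 * sqrt(sum((pred - ref)^2) / sum(ref^2))
}

#' Root mean square error
#'
#' `sqrt(mean((pred - ref)^2))`, in the property's own units. Related to
#' [rsep] by `rsep = 100 * sqrt(n / sum(ref^2)) * rmse`.
#'
#' @inheritParams rsep
#' @return RMSE in property units.
#' @export
rmse <- function(pred, ref) {
  check_pair(pred, ref)
  sqrt(mean((pred - ref)^2))
}

#' Pearson correlation with input validation
#'
#' @param a,b Numeric vectors, length >= 3, neither constant.
#' @return Pearson product-moment correlation.
#' @export
pearson_r <- function(a, b) {
  check_pair(a, b)
  if (length(a) < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input; correlation undefined")
  stats::cor(a, b)
}

check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  if (length(a) < 1L) stop("empty input")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite values in input")
  invisible(TRUE)
}

#' Evaluate predictions against reference values
#'
#' @param property_name Property label.
#' @param set_label `"calibration"` or `"validation"`.
#' @inheritParams rsep
#' @return An `eval_report` row: list with `property_name`, `set_label`,
#'   `rsep_pct`, `rmse`, `r`.
#' @export
evaluate_predictions <- function(property_name, set_label, pred, ref) {
  structure(list(property_name = property_name,
                 set_label = match.arg(set_label, c("calibration", "validation")),
                 rsep_pct = rsep(pred, ref),
                 rmse = rmse(pred, ref),
                 r = pearson_r(pred, ref)),
            class = "eval_report")
}
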