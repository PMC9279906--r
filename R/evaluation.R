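#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y_p - y_r)^2 / \sum(y_r - \bar y)^2}. Not clipped at
#' zero: a predictor worse than the reference mean yields a negative value.
#' The \code{denominator = "predicted"} variant (centring on the predicted
#' values instead of the reference) is available for comparison with
#' sources that typeset the formula that way.
#'
#' @param predicted,reference numeric vectors of equal, nonzero length.
#' @param denominator \code{"reference"} (standard, default) or
#'   \code{"predicted"}.
#' @return R-squared.
#' @export
r_squared <- function(predicted, reference,
                      denominator = c("reference", "predicted")) {
  denominator <- match.arg(denominator)
  if (length(predicted) != length(reference) || length(reference) == 0L)
    stop("`predicted` and `reference` must have equal nonzero length")
  centre <- if (denominator == "reference") reference else predicted
  ss_tot <- sum((centre - mean(reference))^2)
  if (ss_tot == 0) stop("R-squared undefined for a constant reference")
  1 - sum((predicted - reference)^2) / ss_tot
}

#' Root mean square error
#'
#' \eqn{\sqrt{\sum(y_p - y_r)^2 / n}}, in trait units.
#'
#' @param predicted,reference numeric vectors of equal, nonzero length.
#' @return RMSE.
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(reference) == 0L)
    stop("`predicted` and `reference` must have equal nonzero length")
  sqrt(mean((predicted - reference)^2))
}

#' Ratio of performance to deviation
#'
#' \eqn{RPD = SD(y_r) / RMSE} with the n-1 standard deviation. Values above
#' 3 are conventionally read as excellent quantitative prediction, 2-3 as
#' usable screening. A zero RMSE is reported as \code{Inf} with a warning
#' rather than an error, since it arises legitimately from oracle models in
#' tests.
#'
#' @param reference numeric reference values (n >= 2).
#' @param rmse_value RMSE in the same units.
#' @return RPD ratio.
#' @export
rpd <- function(reference, rmse_value) {
  if (length(reference) < 2L) stop("RPD needs at least 2 reference values")
  if (rmse_value < 0) stop("`rmse_value` must be nonnegative")
  if (rmse_value == 0) {
    warning("RMSE is zero; RPD reported as Inf")
    return(Inf)
  }
  stats::sd(reference) / rmse_value
}

#' Evaluate a fitted model over a calibration/validation/prediction split
#'
#' Computes the seven headline statistics of a trait-calibration study:
#' R-squared and RMSE on each of the three splits, plus the RPD of the
#' prediction set (prediction-set reference SD over RMSEP).
#'
#' @param model a fitted model with a \code{predict} method taking a
#'   [spectra_matrix].
#' @param splits a [split_samples] result.
#' @param spectra the full [spectra_matrix] the split indexes into.
#' @param traits numeric trait vector aligned with \code{spectra} rows.
#' @param model_tag,treatment_tag provenance labels carried into the report.
#' @return An object of class \code{eval_report} (also a one-row
#'   data.frame): rc2, rmsec, rv2, rmsev, rp2, rmsep, rpd, n_cal, n_val,
#'   n_pred, model, treatment.
#' @export
evaluate_model <- function(model, splits, spectra, traits,
                           model_tag = class(model)[1],
                           treatment_tag = spectra$treatment) {
  stopifnot(inherits(splits, "split_indices"),
            inherits(spectra, "spectra_matrix"))
  if (length(traits) != nrow(spectra$values))
    stop("`traits` must align with `spectra` rows")
  eval_one <- function(idx) {
    if (!length(idx)) stop("empty split: cannot evaluate")
    pred <- predict(model, spectra[idx, ])
    # R2 is undefined on a degenerate (single-sample or constant) reference
    r2 <- if (length(idx) >= 2L && stats::var(traits[idx]) > 0)
      r_squared(pred, traits[idx]) else NA_real_
    list(r2 = r2, rmse = rmse(pred, traits[idx]), pred = pred)
  }
  cal <- eval_one(splits$calibration)
  val <- if (length(splits$validation)) eval_one(splits$validation) else
    list(r2 = NA_real_, rmse = NA_real_)
  prd <- eval_one(splits$prediction)
  rpd_val <- if (prd$rmse == 0) Inf else rpd(traits[splits$prediction], prd$rmse)
  out <- data.frame(model = model_tag, treatment = treatment_tag,
                    rc2 = cal$r2, rmsec = cal$rmse,
                    rv2 = val$r2, rmsev = val$rmse,
                    rp2 = prd$r2, rmsep = prd$rmse, rpd = rpd_val,
                    n_cal = length(splits$calibration),
                    n_val = length(splits$validation),
                    n_pred = length(splits$prediction),
                    stringsAsFactors = FALSE)
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  if (nrow(x) != 1L) {  # bound reports (e.g. grid results): plain table
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf("<eval_report> %s / %s\n", x$model, x$treatment))
  cat(sprintf("  calibration (n=%d): R2 = %.4f, RMSE = %.4f\n",
              x$n_cal, x$rc2, x$rmsec))
  if (!is.na(x$rv2))
    cat(sprintf("  validation  (n=%d): R2 = %.4f, RMSE = %.4f\n",
                x$n_val, x$rv2, x$rmsev))
  cat(sprintf("  prediction  (n=%d): R2 = %.4f, RMSE = %.4f, RPD = %.4f\n",
              x$n_pred, x$rp2, x$rmsep, x$rpd))
  invisible(x)
}
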