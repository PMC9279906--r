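#' Exponentially decreasing retention ratio
#'
#' The forced-selection schedule of CARS: run i of N retains a fraction
#' \eqn{r_i = a e^{-k i}} of the p wavelengths, with a and k fixed by the
#' boundary conditions \eqn{r_1 = 1} (all wavelengths survive the first
#' run) and \eqn{r_N = 2/p} (two wavelengths survive the last).
#'
#' @param run run index i >= 1.
#' @param total_runs N >= 2.
#' @param n_wavelengths p >= 2.
#' @return Retention ratio in (0, 1].
#' @export
edf_ratio <- function(run, total_runs, n_wavelengths) {
  if (total_runs < 2L) stop("`total_runs` must be >= 2")
  if (n_wavelengths < 2L) stop("`n_wavelengths` must be >= 2")
  if (any(run < 1L) || any(run > total_runs)) stop("`run` out of range")
  k <- log(n_wavelengths / 2) / (total_runs - 1)
  a <- exp(k)
  a * exp(-k * run)
}

#' Competitive adaptive reweighted sampling wavelength selection
#'
#' Monte-Carlo wavelength selection driven by PLS regression-coefficient
#' magnitudes. Each run draws a fraction of the samples, fits PLS1 on the
#' currently retained wavelengths, then eliminates wavelengths in two
#' stages: forced selection keeps the top \eqn{\lceil r_i p\rceil} by
#' absolute coefficient (the exponentially decreasing schedule of
#' [edf_ratio]), and adaptive reweighted sampling draws that many
#' wavelengths with replacement, weighted by absolute coefficient, keeping
#' the distinct survivors. A k-fold cross-validated RMSE of a PLS model on
#' each run's retained set is recorded, and the run minimizing RMSECV
#' defines the selected wavelengths.
#'
#' To avoid information leakage, apply this to calibration samples only.
#'
#' @param spectra a [spectra_matrix] or numeric matrix.
#' @param y trait vector aligned with rows.
#' @param runs number of Monte-Carlo runs N (default 50).
#' @param cv_folds cross-validation folds (default 5).
#' @param mc_fraction fraction of samples drawn per run (default 0.8).
#' @param max_components PLS component ceiling; the count used is chosen by
#'   inner cross-validation (default 10).
#' @param seed integer seed.
#' @return An object of class \code{cars_result}: \code{$selected} (band
#'   indices), \code{$rmsecv_trace}, \code{$retained_history},
#'   \code{$best_run}, \code{$seed}.
#' @export
cars_select <- function(spectra, y, runs = 50L, cv_folds = 5L,
                        mc_fraction = 0.8, max_components = 10L,
                        seed = 1L) {
  X <- .as_values(spectra)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`y` must align with rows of `spectra`")
  if (n < cv_folds) stop("need at least `cv_folds` samples")
  runs <- as.integer(runs)
  if (runs < 1L) stop("`runs` must be >= 1")
  .with_seed(seed, {
    retained <- seq_len(p)
    trace <- numeric(0)
    history <- list()
    for (i in seq_len(runs)) {
      m <- max(2L, round(mc_fraction * n))
      samp <- sample.int(n, m)
      ncomp <- min(max_components, m - 1L, length(retained))
      fit <- .pls1_core(X[samp, retained, drop = FALSE], y[samp], ncomp)
      b <- abs(.pls1_coefs(fit)$coef)
      ratio <- if (runs == 1L) 1 else edf_ratio(i, runs, p)
      keep_n <- min(length(retained), ceiling(ratio * p))
      forced <- retained[order(b, decreasing = TRUE)[seq_len(keep_n)]]
      wts <- b[match(forced, retained)]
      if (sum(wts) == 0) wts <- rep(1, length(forced))
      drawn <- sample(forced, size = keep_n, replace = TRUE, prob = wts)
      retained <- sort(unique(drawn))
      if (length(retained) < 2L) break
      cv <- .pls1_cv(X[, retained, drop = FALSE], y, folds = cv_folds,
                     max_comp = max_components,
                     seed = sample.int(.Machine$integer.max, 1L))
      trace <- c(trace, min(cv$rmsecv))
      history[[length(history) + 1L]] <- retained
    }
    if (!length(history))
      stop("retained set collapsed before any run completed")
    best <- which.min(trace)
    structure(list(selected = history[[best]], rmsecv_trace = trace,
                   retained_history = history, best_run = best,
                   seed = as.integer(seed)),
              class = "cars_result")
  })
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> %d wavelengths selected at run %d/%d (RMSECV %.4g)\n",
              length(x$selected), x$best_run, length(x$rmsecv_trace),
              x$rmsecv_trace[x$best_run]))
  invisible(x)
}

#' Write a CARS result
#'
#' JSON for the full result; optionally a CSV band list (index + nm) that
#' can be applied to any [spectra_matrix] with the same axis.
#'
#' @param result a [cars_select] result.
#' @param path output JSON path.
#' @param csv_path optional band-list CSV path.
#' @param wavelengths band axis in nm for the CSV.
#' @return \code{path}, invisibly.
#' @export
write_cars <- function(result, path, csv_path = NULL, wavelengths = NULL) {
  stopifnot(inherits(result, "cars_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    wl <- if (is.null(wavelengths)) result$selected else
      wavelengths[result$selected]
    utils::write.csv(data.frame(index = result$selected, wavelength_nm = wl),
                     csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Subset a spectra matrix to selected bands
#'
#' @param spectra a [spectra_matrix].
#' @param selected integer band indices (e.g. from [cars_select]).
#' @return A [spectra_matrix] restricted to the selected bands.
#' @export
apply_bands <- function(spectra, selected) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (inherits(selected, "cars_result")) selected <- selected$selected
  spectra[, selected]
}
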