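#' Kennard-Stone sample selection
#'
#' Deterministic max-min-distance selection of a representative subset:
#' the first two picks are the pair at maximum Euclidean distance; every
#' later pick maximizes the minimum distance to the already-selected set.
#' Ties are broken toward the lowest sample index so the result is fully
#' deterministic.
#'
#' @param spectra a [spectra_matrix] or numeric matrix (rows = samples).
#' @param n_select number of samples to select, \code{2 <= n_select <= n}.
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(spectra, n_select) {
  X <- .as_values(spectra)
  n <- nrow(X)
  n_select <- as.integer(n_select)
  if (n_select < 2L) stop("`n_select` must be at least 2")
  if (n_select > n) stop("`n_select` exceeds the number of samples")
  D <- unname(as.matrix(stats::dist(X)))
  # seed pair: maximum distance, ties -> smallest (i, j)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- which.max(D[i, (i + 1L):n]) + i  # first max within row
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  if (n_select > 2L) {
    mind <- pmin(D[, sel[1]], D[, sel[2]])
    mind[sel] <- -Inf
    for (k in 3:n_select) {
      nxt <- which.max(mind)  # which.max returns the first (lowest index) max
      sel <- c(sel, nxt)
      mind <- pmin(mind, D[, nxt])
      mind[nxt] <- -Inf
    }
  }
  sel
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Calibration / validation / prediction split
#'
#' Partitions samples the way chemometric trait-calibration studies do:
#' Kennard-Stone selects a representative calibration pool at the given
#' calibration:prediction ratio (default 2:1), the remainder becomes the
#' prediction set, and a random fraction of the pool (default 15%) is
#' carved out as the validation set used for hyperparameter tuning. Counts
#' are rounded half away from zero, so n = 387 yields 219/39/129.
#'
#' @param spectra a [spectra_matrix] or matrix.
#' @param cal_pred_ratio calibration:prediction ratio as a length-2 numeric
#'   (default \code{c(2, 1)}).
#' @param val_fraction fraction of the calibration pool drawn (uniformly,
#'   without replacement) as validation (default 0.15).
#' @param seed integer seed for the random carve-out.
#' @return An object of class \code{split_indices} with integer index sets
#'   \code{$calibration}, \code{$validation}, \code{$prediction}.
#' @export
split_samples <- function(spectra, cal_pred_ratio = c(2, 1),
                          val_fraction = 0.15, seed = 1L) {
  X <- .as_values(spectra)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples to split")
  frac <- cal_pred_ratio[1] / sum(cal_pred_ratio)
  pool_n <- as.integer(.round_half_away(n * frac))
  if (pool_n < 2L || pool_n >= n)
    stop("`cal_pred_ratio` produces an empty calibration or prediction set")
  pool <- sort(kennard_stone(X, pool_n))
  prediction <- setdiff(seq_len(n), pool)
  val_n <- as.integer(.round_half_away(val_fraction * pool_n))
  if (val_n >= pool_n)
    stop("`val_fraction` leaves no calibration samples")
  validation <- integer(0)
  if (val_n > 0L) {
    validation <- sort(.with_seed(seed, sample(pool, val_n)))
  }
  structure(list(calibration = setdiff(pool, validation),
                 validation = validation,
                 prediction = prediction,
                 seed = as.integer(seed),
                 params = list(cal_pred_ratio = cal_pred_ratio,
                               val_fraction = val_fraction)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> calibration %d / validation %d / prediction %d (seed %d)\n",
              length(x$calibration), length(x$validation),
              length(x$prediction), x$seed))
  invisible(x)
}

#' Write a split to JSON
#' @param split a [split_samples] result.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_indices"))
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG so seeded package internals never perturb user code.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
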