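#' @name pretreatments
#' @title Spectral pretreatments
#'
#' @description Per-sample transforms applied to a [spectra_matrix] before
#' multivariate modelling: moving window smoothing (MWS), Savitzky-Golay
#' filtering (SG), first/second finite-difference derivatives (FDR/SDR) and
#' wavelet-transform denoising (WT). All operate row-wise and preserve the
#' band count, so models stay comparable across treatments.
NULL

.map_rows <- function(spectra, fn, tag) {
  x <- if (inherits(spectra, "spectra_matrix")) spectra else
    spectra_matrix(.as_values(spectra))
  out <- t(apply(x$values, 1L, fn))
  if (nrow(x$values) == 1L) out <- matrix(out, nrow = 1L)
  spectra_matrix(out, x$wavelengths, x$ids, treatment = tag)
}

#' Moving window smoothing
#'
#' Replaces each band by the mean of a window centred on it; at the spectrum
#' edges the window shrinks symmetrically so the estimate stays centred.
#'
#' @param spectra a [spectra_matrix] (or plain matrix/vector).
#' @param window odd positive window width in bands (default 5).
#' @return A [spectra_matrix] tagged \code{"MWS"}.
#' @export
mws <- function(spectra, window = 5L) {
  window <- as.integer(window)
  if (window <= 0L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer")
  nb <- ncol(.as_values(spectra))
  if (window > nb) stop("`window` exceeds the number of bands")
  half <- (window - 1L) %/% 2L
  .map_rows(spectra, function(v) {
    B <- length(v)
    vapply(seq_len(B), function(i) {
      k <- min(half, i - 1L, B - i)
      mean(v[(i - k):(i + k)])
    }, numeric(1))
  }, "MWS")
}

#' Savitzky-Golay filtering
#'
#' Local least-squares polynomial smoothing (and optional differentiation)
#' that preserves peak shape and width while suppressing noise. Edges are
#' handled by evaluating the window polynomial at off-centre positions.
#' Derivatives are per band index (the wavelength grid is uniform, so a
#' division by the band spacing is a constant factor).
#'
#' @param spectra a [spectra_matrix].
#' @param window odd window width (default 11).
#' @param order polynomial degree, \code{order < window} (default 2).
#' @param deriv derivative order 0..2, \code{deriv <= order}.
#' @return A [spectra_matrix] tagged \code{"SG"}.
#' @export
savgol <- function(spectra, window = 11L, order = 2L, deriv = 0L) {
  window <- as.integer(window); order <- as.integer(order)
  deriv <- as.integer(deriv)
  if (window <= 0L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer")
  if (order >= window) stop("`order` must be smaller than `window`")
  if (deriv < 0L || deriv > 2L || deriv > order)
    stop("`deriv` must be in 0..2 and not exceed `order`")
  .map_rows(spectra, function(v)
    signal::sgolayfilt(v, p = order, n = window, m = deriv, ts = 1), "SG")
}

#' Finite-difference derivative spectra
#'
#' First-order (FDR) and second-order (SDR) derivative pretreatments as
#' plain forward differences, unscaled by the band spacing. The tail is
#' padded by repeating the last difference so the band count is preserved.
#' These are listed separately from Savitzky-Golay derivatives because they
#' are a distinct, rougher pretreatment that amplifies band-to-band
#' variation.
#'
#' @param spectra a [spectra_matrix].
#' @param order 1 (FDR) or 2 (SDR).
#' @return A [spectra_matrix] tagged \code{"FDR"} or \code{"SDR"}.
#' @export
derivative <- function(spectra, order = 1L) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2")
  nb <- ncol(.as_values(spectra))
  if (nb < order + 1L) stop("too few bands for a derivative of order ", order)
  d1 <- function(v) { d <- diff(v); c(d, d[length(d)]) }
  fn <- if (order == 1L) d1 else function(v) d1(d1(v))
  .map_rows(spectra, fn, if (order == 1L) "FDR" else "SDR")
}

# ---- discrete wavelet transform (periodized, orthogonal) -----------------
# Daubechies filters; db4 = 4 vanishing moments, 8 taps (standard values).
.wt_filters <- function(family) {
  lo <- switch(family,
    haar = c(0.70710678118654746, 0.70710678118654746),
    db2 = c(0.48296291314469025, 0.83651630373746899,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330889651, 0.71484657055291567,
            0.63088076792985892, -0.027983769416859854,
            -0.18703481171909309, 0.030841381835560764,
            0.032883011666885197, -0.010597401785069032),
    stop("unsupported wavelet family: ", family))
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)  # quadrature mirror
  list(lo = lo, hi = hi, L = L)
}

.dwt_step <- function(v, f) {
  n <- length(v)
  idx <- outer(seq(1L, n, by = 2L), 0:(f$L - 1L), `+`)
  idx <- (idx - 1L) %% n + 1L
  M <- matrix(v[idx], ncol = f$L)
  list(a = as.vector(M %*% f$lo), d = as.vector(M %*% f$hi))
}

.idwt_step <- function(a, d, f) {
  n2 <- 2L * length(a)
  out <- numeric(n2)
  for (k in seq_along(a)) {
    pos <- ((2L * (k - 1L) + 0:(f$L - 1L)) %% n2) + 1L
    out[pos] <- out[pos] + a[k] * f$lo + d[k] * f$hi
  }
  out
}

.dwt <- function(v, f, level) {
  details <- vector("list", level)
  a <- v
  for (j in seq_len(level)) {
    s <- .dwt_step(a, f)
    a <- s$a
    details[[j]] <- s$d
  }
  list(a = a, d = details)
}

.idwt <- function(coeffs, f) {
  a <- coeffs$a
  for (j in rev(seq_along(coeffs$d))) a <- .idwt_step(a, coeffs$d[[j]], f)
  a
}

#' Wavelet-transform denoising
#'
#' Periodized orthogonal discrete wavelet decomposition, soft thresholding
#' of the detail coefficients, and reconstruction. The default rule is the
#' universal threshold \eqn{\sigma\sqrt{2\ln B}} with \eqn{\sigma}
#' estimated from the median absolute deviation of the finest-scale
#' details. Spectra whose band count is not a multiple of \eqn{2^{level}}
#' are reflection-padded before the transform and truncated after.
#'
#' @param spectra a [spectra_matrix].
#' @param family \code{"db4"} (default), \code{"db2"} or \code{"haar"}.
#' @param level decomposition depth (default 3).
#' @param rule \code{"universal"} soft thresholding (default) or
#'   \code{"none"} (pure analysis/synthesis; useful to verify perfect
#'   reconstruction).
#' @return A [spectra_matrix] tagged \code{"WT"}.
#' @export
wavelet_denoise <- function(spectra, family = "db4", level = 3L,
                            rule = c("universal", "none")) {
  rule <- match.arg(rule)
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1")
  f <- .wt_filters(family)
  nb <- ncol(.as_values(spectra))
  if (nb %/% 2L^level < 1L)
    stop("decomposition level ", level, " infeasible for ", nb, " bands")
  block <- 2L^level
  pad <- (block - nb %% block) %% block
  .map_rows(spectra, function(v) {
    vp <- if (pad > 0L) c(v, rev(v)[seq_len(pad)]) else v
    cf <- .dwt(vp, f, level)
    if (rule == "universal") {
      finest <- cf$d[[1]]
      sigma <- stats::median(abs(finest - stats::median(finest))) / 0.6745
      thr <- sigma * sqrt(2 * log(length(vp)))
      cf$d <- lapply(cf$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
    }
    .idwt(cf, f)[seq_len(length(v))]
  }, "WT")
}

#' Apply a named pretreatment
#'
#' Dispatch helper used by the pipeline: maps a treatment tag to the
#' corresponding pretreatment with its default parameters.
#'
#' @param spectra a [spectra_matrix].
#' @param treatment one of \code{"raw"}, \code{"MWS"}, \code{"SG"},
#'   \code{"FDR"}, \code{"SDR"}, \code{"WT"}.
#' @param ... passed through to the pretreatment function.
#' @return A [spectra_matrix].
#' @export
pretreat <- function(spectra, treatment, ...) {
  switch(treatment,
    raw = spectra,
    MWS = mws(spectra, ...),
    SG = savgol(spectra, ...),
    FDR = derivative(spectra, 1L),
    SDR = derivative(spectra, 2L),
    WT = wavelet_denoise(spectra, ...),
    stop("unknown pretreatment: ", treatment))
}
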