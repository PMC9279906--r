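#' Endmember set
#'
#' Reference pure-class spectra for spectral angle mapper classification.
#' Any number (k >= 1) of endmembers is allowed; the conventional canopy
#' workflow uses six roles (top/middle/bottom point and region), which are
#' ordinary labels here.
#'
#' @param spectra k x B matrix of reference reflectance spectra (or a single
#'   vector), all nonzero.
#' @param labels class tag per spectrum: \code{"plant"} or
#'   \code{"background"}.
#' @return An object of class \code{endmember_set}.
#' @export
endmember_set <- function(spectra, labels = NULL) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1L)
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 1L) stop("at least one endmember required")
  norms <- sqrt(rowSums(spectra^2))
  if (any(norms == 0)) stop("endmember spectra must be nonzero")
  if (is.null(labels)) labels <- rep("plant", nrow(spectra))
  labels <- match.arg(labels, c("plant", "background"), several.ok = TRUE)
  if (length(labels) != nrow(spectra)) stop("one label per endmember required")
  if (!any(labels == "plant")) stop("at least one plant endmember required")
  structure(list(spectra = spectra, labels = labels), class = "endmember_set")
}

#' Spectral angle between two spectra
#'
#' The angle \eqn{\arccos(\langle t,r\rangle / (\|t\|\|r\|))} in radians,
#' in \eqn{[0, \pi]}. Scale-invariant in both arguments, which is what makes
#' the spectral angle mapper robust to illumination differences across a
#' canopy.
#'
#' @param test,reference numeric spectra of equal length, both nonzero.
#' @return Angle in radians.
#' @export
spectral_angle <- function(test, reference) {
  if (length(test) != length(reference))
    stop("spectra must have equal length")
  nt <- sqrt(sum(test^2)); nr <- sqrt(sum(reference^2))
  if (nt == 0 || nr == 0) stop("spectral angle undefined for a zero vector")
  acos(max(-1, min(1, sum(test * reference) / (nt * nr))))
}

#' Spectral angle mapper canopy classification
#'
#' Classifies every pixel of a calibrated cube against the endmembers.
#' A pixel is plant iff its minimum angle over plant endmembers is below
#' \code{threshold} and, when background endmembers are supplied, strictly
#' smaller than its minimum angle to any background endmember (ties go to
#' background, keeping the canopy mask conservative). The angle is computed
#' over the full band vector. Pixels with non-finite (masked) values are
#' never plant.
#'
#' @param cube a calibrated [hypercube].
#' @param endmembers an [endmember_set] with matching band count.
#' @param threshold maximum plant angle in radians (default 0.10).
#' @return An object of class \code{canopy_mask}: \code{mask} (logical
#'   lines x samples) and \code{angle_map} (minimum plant angle, radians).
#' @export
classify_sam <- function(cube, endmembers, threshold = 0.10) {
  stopifnot(inherits(cube, "hypercube"), inherits(endmembers, "endmember_set"))
  if (!isTRUE(cube$meta$calibrated))
    stop("classify_sam requires a calibrated cube")
  d <- dim(cube$data)
  if (ncol(endmembers$spectra) != d[3])
    stop("endmember band count does not match the cube")
  P <- matrix(cube$data, d[1] * d[2], d[3])  # pixel-major, band columns
  pn <- sqrt(rowSums(P^2))
  E <- endmembers$spectra / sqrt(rowSums(endmembers$spectra^2))
  cosang <- (P %*% t(E)) / pn
  cosang[!is.finite(cosang)] <- -1  # masked / zero pixels: maximal angle
  ang <- acos(pmin(pmax(cosang, -1), 1))
  is_plant_col <- endmembers$labels == "plant"
  min_plant <- apply(ang[, is_plant_col, drop = FALSE], 1L, min)
  mask <- min_plant < threshold
  if (any(!is_plant_col)) {
    min_bg <- apply(ang[, !is_plant_col, drop = FALSE], 1L, min)
    mask <- mask & (min_plant < min_bg)
  }
  structure(list(mask = matrix(mask, d[1], d[2]),
                 angle_map = matrix(min_plant, d[1], d[2]),
                 threshold = threshold),
            class = "canopy_mask")
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat(sprintf("<canopy_mask> %d x %d, %d plant pixels (threshold %.4g rad)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold))
  invisible(x)
}

#' Mean canopy spectrum
#'
#' Arithmetic per-band mean over the masked (plant) pixels. Non-plant
#' pixels are excluded from the average (rather than contributing zeros,
#' which would scale the mean by canopy fraction), and so are pixels with
#' masked-invalid calibration values.
#'
#' @param cube a [hypercube].
#' @param mask a [canopy_mask] or logical matrix matching the cube's
#'   spatial layout.
#' @return Numeric spectrum of length B.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  d <- dim(cube$data)
  if (!identical(dim(m), d[1:2])) stop("mask layout does not match the cube")
  P <- matrix(cube$data, d[1] * d[2], d[3])
  keep <- as.vector(m) & apply(is.finite(P), 1L, all)
  if (!any(keep)) stop("empty ROI: no valid plant pixels under the mask")
  colMeans(P[keep, , drop = FALSE])
}

#' Read endmember spectra from CSV
#'
#' Expected layout: a \code{label} column then one reflectance column per
#' band (header row holds the wavelengths).
#'
#' @param path CSV path.
#' @return An [endmember_set]; wavelengths attached as an attribute.
#' @export
read_endmembers <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  em <- endmember_set(as.matrix(df[, -1, drop = FALSE]), df[[1]])
  attr(em, "wavelengths") <- as.numeric(names(df)[-1])
  em
}

#' Write a canopy mask
#'
#' Writes the mask as an 8-bit PNG (0/255) and/or a CSV of 0/1, and
#' optionally the angle map as CSV.
#'
#' @param mask a [canopy_mask].
#' @param png_path,csv_path,angle_csv_path output paths (NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_mask <- function(mask, png_path = NULL, csv_path = NULL,
                       angle_csv_path = NULL) {
  stopifnot(inherits(mask, "canopy_mask"))
  written <- character(0)
  if (!is.null(png_path)) {
    png::writePNG(mask$mask * 1, png_path)
    written <- c(written, png_path)
  }
  if (!is.null(csv_path)) {
    utils::write.table(mask$mask * 1L, csv_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(angle_csv_path)) {
    utils::write.table(mask$angle_map, angle_csv_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, angle_csv_path)
  }
  invisible(written)
}
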