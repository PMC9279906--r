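#' Hyperspectral cube
#'
#' An in-memory Vis-NIR hyperspectral image: a 3-D array of raw digital
#' numbers or reflectance, ordered \code{[lines, samples, bands]}, plus the
#' band-centre wavelength axis and acquisition metadata.
#'
#' @param data 3-D numeric array \code{[lines x samples x bands]}.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, one per band.
#' @param calibrated logical; \code{TRUE} once white/dark reflectance
#'   calibration has been applied.
#' @param meta named list of extra acquisition metadata (exposure,
#'   interleave of origin, ...).
#' @return An object of class \code{hypercube}.
#' @export
hypercube <- function(data, wavelengths = NULL, calibrated = FALSE,
                      meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [lines x samples x bands]")
  nb <- dim(data)[3L]
  if (is.null(wavelengths))
    wavelengths <- seq(400, 1000, length.out = nb)
  if (length(wavelengths) != nb)
    stop("length(wavelengths) must equal the band dimension (", nb, ")")
  if (nb > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (!calibrated && any(data[is.finite(data)] < 0))
    stop("raw digital numbers must be nonnegative")
  structure(
    list(data = data, wavelengths = as.numeric(wavelengths),
         meta = c(list(calibrated = isTRUE(calibrated)), meta)),
    class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (isTRUE(x$meta$calibrated)) "calibrated reflectance" else "raw DN"))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# ENVI numeric data type codes used on disk
.envi_dtypes <- list(`4` = list(what = "numeric", size = 4L),
                     `5` = list(what = "numeric", size = 8L))

.envi_paths <- function(path) {
  # accept either the header or the binary path; derive the companion
  if (grepl("\\.hdr$", path)) {
    hdr <- path
    bin <- sub("\\.hdr$", "", path)
    if (!file.exists(bin)) bin <- paste0(bin, ".dat")
  } else {
    bin <- path
    hdr <- paste0(path, ".hdr")
    if (!file.exists(hdr)) hdr <- sub("\\.[^.]+$", ".hdr", path)
  }
  list(hdr = hdr, bin = bin)
}

.parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[[1]]))
    stop("not an ENVI header: ", hdr_path)
  # join multi-line { ... } blocks
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  # strip brace blocks first, capturing them
  pat <- "([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*\\{([^}]*)\\}"
  m <- gregexpr(pat, txt)
  for (s in regmatches(txt, m)[[1]]) {
    key <- tolower(trimws(sub(pat, "\\1", s)))
    val <- trimws(sub(pat, "\\2", s))
    out[[key]] <- val
  }
  txt2 <- gsub(pat, "", txt)
  for (ln in strsplit(txt2, "\n")[[1]]) {
    if (!grepl("=", ln)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- tolower(trimws(kv[[1]]))
    if (nchar(key)) out[[key]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Read an ENVI hyperspectral cube
#'
#' Reads an ENVI header (\code{.hdr}) plus flat little-endian binary cube in
#' BSQ, BIL or BIP interleave. Wavelengths are taken from the header's
#' \code{wavelength} block when present, otherwise synthesized evenly over
#' 400-1000 nm.
#'
#' @param path path to the header or the binary file.
#' @return A [hypercube].
#' @export
read_cube <- function(path) {
  p <- .envi_paths(path)
  if (!file.exists(p$hdr)) stop("ENVI header not found: ", p$hdr)
  if (!file.exists(p$bin)) stop("ENVI binary not found: ", p$bin)
  h <- .parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands")
  if (!all(need %in% names(h)))
    stop("ENVI header missing required fields: ",
         paste(setdiff(need, names(h)), collapse = ", "))
  ns <- as.integer(h$samples); nl <- as.integer(h$lines); nb <- as.integer(h$bands)
  interleave <- tolower(if (is.null(h$interleave)) "bsq" else h$interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported ENVI interleave: ", interleave)
  dtype <- as.character(if (is.null(h[["data type"]])) "5" else h[["data type"]])
  dt <- .envi_dtypes[[dtype]]
  if (is.null(dt)) stop("unsupported ENVI data type: ", dtype)
  n <- as.double(ns) * nl * nb
  expect_bytes <- n * dt$size
  actual <- file.info(p$bin)$size
  if (!isTRUE(actual == expect_bytes))
    stop(sprintf("ENVI binary size mismatch: header implies %.0f bytes, file has %.0f",
                 expect_bytes, actual))
  con <- file(p$bin, "rb"); on.exit(close(con))
  v <- readBin(con, what = dt$what, n = n, size = dt$size, endian = "little")
  arr <- switch(interleave,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1)))
  wl <- NULL
  if (!is.null(h$wavelength)) {
    wl <- as.numeric(strsplit(h$wavelength, ",")[[1]])
    if (length(wl) != nb) stop("header wavelength count disagrees with bands")
  }
  calibrated <- isTRUE(as.integer(h[["calibration state"]] %||% "0") == 1L)
  hypercube(arr, wavelengths = wl, calibrated = calibrated,
            meta = list(interleave = interleave, source = p$bin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hypercube in ENVI format
#'
#' Writes the header and a little-endian 64-bit float binary. BSQ is the
#' canonical layout; BIL and BIP are also supported so round-trips can be
#' tested across interleaves.
#'
#' @param cube a [hypercube].
#' @param path output path for the binary; \code{<path>.hdr} is written
#'   alongside.
#' @param interleave one of \code{"bsq"}, \code{"bil"}, \code{"bip"}.
#' @return \code{path}, invisibly.
#' @export
write_cube <- function(cube, path, interleave = "bsq") {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- tolower(interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("unsupported ENVI interleave: ", interleave)
  d <- dim(cube$data)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("calibration state = ", as.integer(isTRUE(cube$meta$calibrated))),
           paste0("wavelength = { ",
                  paste(sprintf("%.17g", cube$wavelengths), collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(v), con, size = 8L, endian = "little")
  invisible(path)
}

#' White/dark reference pair
#'
#' Holds the white-panel and dark-current reference images used for
#' reflectance calibration. Push-broom systems calibrate per detector
#' column, so 3-D references are collapsed to per-column (sample x band)
#' means by default; a full cube matching the target layout is also
#' accepted (\code{collapse = FALSE}).
#'
#' @param white,dark 2-D \code{[samples x bands]} or 3-D
#'   \code{[lines x samples x bands]} arrays of digital numbers.
#' @param collapse collapse 3-D references to per-column means.
#' @return An object of class \code{reference_pair}.
#' @export
reference_pair <- function(white, dark, collapse = TRUE) {
  squash <- function(a) {
    if (length(dim(a)) == 3L && collapse) apply(a, c(2, 3), mean) else a
  }
  white <- squash(white); dark <- squash(dark)
  if (!identical(dim(white), dim(dark)))
    stop("white and dark references must share a layout")
  structure(list(white = white, dark = dark), class = "reference_pair")
}

#' Reflectance calibration against white and dark references
#'
#' Converts raw digital numbers to relative reflectance,
#' \eqn{R = (R_{raw} - R_d) / (R_w - R_d)}, the standard flat-field
#' correction against a high-reflectance white panel and the sensor dark
#' current. Positions where the white and dark references coincide carry no
#' radiometric information and are masked \code{NA}; reflectance is not
#' clipped, so specular values above 1 pass through.
#'
#' @param raw an uncalibrated [hypercube] of digital numbers.
#' @param refs a [reference_pair].
#' @return A calibrated [hypercube] with the calibration flag set.
#' @export
calibrate <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_pair"))
  if (isTRUE(raw$meta$calibrated))
    stop("cube is already calibrated; refusing to double-apply")
  d <- dim(raw$data)
  expand <- function(a) {
    if (length(dim(a)) == 2L) {
      if (!identical(dim(a), d[2:3]))
        stop("reference layout [", paste(dim(a), collapse = "x"),
             "] does not match cube [", paste(d[2:3], collapse = "x"), "]")
      aperm(array(a, c(d[2], d[3], d[1])), c(3, 1, 2))
    } else {
      if (!identical(dim(a), d))
        stop("full-cube reference dimensions do not match the cube")
      a
    }
  }
  w <- expand(refs$white); k <- expand(refs$dark)
  denom <- w - k
  if (all(denom == 0)) stop("degenerate references: white equals dark everywhere")
  out <- (raw$data - k) / denom
  out[denom == 0] <- NA_real_
  hypercube(out, raw$wavelengths, calibrated = TRUE,
            meta = raw$meta[setdiff(names(raw$meta), "calibrated")])
}
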