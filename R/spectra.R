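#' Spectra matrix
#'
#' An n-samples by B-bands table of reflectance (or derivative) spectra with
#' its wavelength axis, sample identifiers and a pretreatment provenance
#' tag. This is the object every pretreatment, selection and modelling step
#' consumes and returns.
#'
#' @param values numeric matrix, one row per sample, one column per band.
#' @param wavelengths band centres in nm, strictly increasing.
#' @param ids character sample identifiers, unique, one per row.
#' @param treatment provenance tag, e.g. \code{"raw"}, \code{"MWS"},
#'   \code{"SG"}, \code{"FDR"}, \code{"SDR"}, \code{"WT"}.
#' @return An object of class \code{spectra_matrix}.
#' @export
spectra_matrix <- function(values, wavelengths = NULL, ids = NULL,
                           treatment = "raw") {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("a spectra matrix needs at least one sample")
  nb <- ncol(values)
  if (is.null(wavelengths)) wavelengths <- seq(400, 1000, length.out = nb)
  if (length(wavelengths) != nb)
    stop("length(wavelengths) must equal the number of bands")
  if (nb > 1L && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) stop("one id per sample required")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  dimnames(values) <- NULL
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 ids = ids, treatment = treatment),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d bands (%.1f-%.1f nm), treatment: %s\n",
              nrow(x$values), ncol(x$values), min(x$wavelengths),
              max(x$wavelengths), x$treatment))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$values)

#' Subset a spectra matrix
#'
#' @param x a [spectra_matrix].
#' @param i sample (row) index.
#' @param j band (column) index.
#' @param ... unused.
#' @export
`[.spectra_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  spectra_matrix(x$values[i, j, drop = FALSE], x$wavelengths[j], x$ids[i],
                 x$treatment)
}

.as_values <- function(x) {
  if (inherits(x, "spectra_matrix")) x$values
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), nrow = 1L)
}

#' Write spectra to CSV
#'
#' One header row (\code{id} then the wavelengths) and one row per sample.
#' Floats are written at 17 significant digits so [read_spectra] inverts
#' the write bit-compatibly.
#'
#' @param spectra a [spectra_matrix].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (nrow(spectra$values) < 1L || ncol(spectra$values) < 1L)
    stop("refusing to write an empty spectra matrix")
  hdr <- paste(c("id", sprintf("%.17g", spectra$wavelengths)), collapse = ",")
  rows <- vapply(seq_len(nrow(spectra$values)), function(i) {
    paste(c(spectra$ids[i], sprintf("%.17g", spectra$values[i, ])),
          collapse = ",")
  }, character(1))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Inverse of [write_spectra].
#'
#' @param path CSV path.
#' @param treatment provenance tag to attach.
#' @return A [spectra_matrix].
#' @export
read_spectra <- function(path, treatment = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("spectra CSV needs an id column plus bands")
  wl <- as.numeric(names(df)[-1])
  vals <- apply(df[, -1, drop = FALSE], 2L, as.numeric)
  vals <- matrix(as.numeric(vals), nrow = nrow(df))
  spectra_matrix(vals, wl, df[[1]], treatment = treatment)
}
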