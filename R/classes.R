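#' Construct a spectrum
#'
#' The unit record of all spectral arithmetic in the package: a strictly
#' increasing wavelength axis in nanometres paired with a reflectance
#' vector (unitless, nominally in \[0, ~1.2\] after calibration).
#'
#' @param wavelengths numeric vector of wavelengths (nm), strictly increasing.
#' @param values numeric reflectance vector, same length as `wavelengths`.
#' @return An object of class `spectrum`: a list with elements
#'   `wavelengths` and `values`.
#' @export
#' @examples
#' s <- spectrum(c(500, 600, 700), c(0.1, 0.2, 0.5))
#' print(s)
spectrum <- function(wavelengths, values) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have equal length")
  if (length(wavelengths) == 0L)
    stop("spectrum must contain at least one band")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(wavelengths)))
    stop("wavelengths must be finite")
  structure(list(wavelengths = wavelengths, values = values),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bands, %.2f-%.2f nm, reflectance [%.4g, %.4g]\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelengths)

#' @export
plot.spectrum <- function(x, ..., xlab = "Wavelength (nm)",
                          ylab = "Reflectance", type = "l") {
  plot(x$wavelengths, x$values, xlab = xlab, ylab = ylab, type = type, ...)
}

#' Construct a hyperspectral cube
#'
#' A rows x cols x bands reflectance array with its wavelength axis and an
#' optional boolean foreground mask.
#'
#' @param data 3-D numeric array, `rows x cols x bands`.
#' @param wavelengths wavelength axis (nm); length must equal `dim(data)[3]`.
#' @param mask optional logical matrix, `rows x cols`; `TRUE` marks plant
#'   (foreground) pixels.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, mask = NULL) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("band count must equal wavelength count")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(data)[1:2]))
      stop("mask shape must equal the cube's spatial shape")
    storage.mode(mask) <- "logical"
  }
  structure(list(data = data, wavelengths = wavelengths, mask = mask),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.2f-%.2f nm)%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (is.null(x$mask)) "" else
                sprintf(", mask: %d foreground px", sum(x$mask))))
  invisible(x)
}

#' Resolve a wavelength to a band index
#'
#' Finds the nearest band on a wavelength axis. Lookup is tolerant to half
#' the instrument's spectral resolution: a requested wavelength farther than
#' `tol` nm from every band is an error rather than a silent approximation.
#'
#' @param wavelengths wavelength axis (nm).
#' @param nm requested wavelength(s) in nm.
#' @param tol maximum |axis - nm| accepted, in nm (default 1.5).
#' @return Integer index (or vector of indices) into `wavelengths`.
#' @export
band_index <- function(wavelengths, nm, tol = 1.5) {
  vapply(nm, function(w) {
    i <- which.min(abs(wavelengths - w))
    if (abs(wavelengths[i] - w) > tol)
      stop(sprintf("no band within %.2f nm of %.2f nm (nearest: %.2f nm)",
                   tol, w, wavelengths[i]))
    as.integer(i)
  }, integer(1))
}

#' Construct a samples-by-features table
#'
#' Container pairing a feature matrix (spectral bands or chlorophyll
#' fluorescence parameters) with the response (shikimic acid concentration)
#' and the experimental design metadata.
#'
#' @param X numeric matrix, samples x features, with column names.
#' @param y numeric response vector (shikimate), or NULL.
#' @param meta data.frame of design metadata (plant_id, genotype,
#'   treatment, day), one row per sample, or NULL.
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(X, y = NULL, meta = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(y) && length(y) != nrow(X))
    stop("response length must equal row count")
  if (!is.null(meta) && nrow(meta) != nrow(X))
    stop("metadata row count must equal sample count")
  structure(list(X = X, y = y, meta = meta), class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d features%s%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y)) "" else ", with response",
              if (is.null(x$meta)) "" else
                paste0(", meta: ", paste(names(x$meta), collapse = "/"))))
  invisible(x)
}

#' @export
as.data.frame.sample_table <- function(x, ...) {
  out <- as.data.frame(x$X)
  if (!is.null(x$y)) out <- cbind(shikimate = x$y, out)
  if (!is.null(x$meta)) out <- cbind(x$meta, out)
  out
}

#' Write a sample table to CSV
#'
#' Layout: design metadata columns first (plant_id, genotype, treatment,
#' day), then the response, then one column per feature.
#'
#' @param tab a [sample_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Read a sample table written by [write_sample_table()]
#'
#' @param path CSV path.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("plant_id", "genotype", "treatment", "day"),
                         names(df))
  y <- if ("shikimate" %in% names(df)) df$shikimate else NULL
  feat <- setdiff(names(df), c(meta_cols, "shikimate"))
  sample_table(as.matrix(df[feat]),
               y = y,
               meta = if (length(meta_cols)) df[meta_cols] else NULL)
}

# run a block under a fixed seed without disturbing the caller's RNG state;
# seed = NULL draws from the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
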