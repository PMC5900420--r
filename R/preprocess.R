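#' Dark/white reflectance calibration
#'
#' Converts raw counts to relative reflectance with the standard two-point
#' correction `R = (raw - dark) / (white - dark)`, element-wise over the
#' whole cube.
#'
#' @param raw,white,dark [hypercube()]s of raw counts with identical shapes
#'   and wavelength axes.
#' @return A [hypercube()] of reflectance.
#' @export
reflectance_calibrate <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(dark, "hypercube"))
  if (!all(dim(raw$data) == dim(white$data)) ||
      !all(dim(raw$data) == dim(dark$data)))
    stop("raw, white and dark cubes must share the same shape")
  denom <- white$data - dark$data
  nz <- sum(denom == 0)
  if (nz > 0)
    stop(sprintf("white - dark is zero at %d voxel(s); cannot calibrate", nz))
  hypercube((raw$data - dark$data) / denom, raw$wavelengths, raw$mask)
}

#' Segment the plant from the background
#'
#' Band-ratio vegetation segmentation: a pixel is foreground when
#' `R(nir) / R(red) > ratio_threshold`. Green canopies have a strong NIR
#' plateau and deep red absorption, so the ratio separates plant from soil
#' and conveyor background. Of the pixels passing the threshold, only the
#' largest 4-connected component is retained, which drops isolated
#' speckle.
#'
#' @param cube a reflectance [hypercube()].
#' @param red_nm,nir_nm band positions in nm (defaults 670 and 800).
#' @param ratio_threshold NIR/red ratio above which a pixel is plant
#'   (default 2).
#' @return Logical foreground matrix (`rows x cols`).
#' @export
segment_plant <- function(cube, red_nm = 670, nir_nm = 800,
                          ratio_threshold = 2) {
  stopifnot(inherits(cube, "hypercube"))
  ir <- band_index(cube$wavelengths, red_nm)
  ii <- band_index(cube$wavelengths, nir_nm)
  red <- cube$data[, , ir]
  nir <- cube$data[, , ii]
  ratio <- nir / pmax(red, .Machine$double.eps)
  mask <- ratio > ratio_threshold
  if (!any(mask))
    stop("segmentation produced an empty mask: no pixel exceeds the ratio threshold")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  lab == keep
}

#' Mean spectrum over a region of interest
#'
#' Arithmetic per-band mean of all pixels inside the mask; the reflectance
#' of the whole plant collapses to one spectrum per plant, the sample unit
#' of all downstream chemometrics.
#'
#' @param cube a [hypercube()].
#' @param mask logical foreground matrix; defaults to the cube's own mask.
#' @return A [spectrum()].
#' @export
mean_roi_spectrum <- function(cube, mask = cube$mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(mask)) stop("no mask supplied and the cube carries none")
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask is empty")
  d <- dim(cube$data)
  m <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  spectrum(cube$wavelengths, colMeans(m[mask, , drop = FALSE]))
}

#' Crop a spectrum to a wavelength window
#'
#' Retains bands with `lo <= wavelength <= hi` (closed interval). Used to
#' discard the noisy extremes of the detector range before analysis.
#'
#' @param s a [spectrum()].
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return A [spectrum()] restricted to the window.
#' @export
crop_spectrum <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectrum"), lo < hi)
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  if (!any(keep)) stop("no bands inside the requested window")
  spectrum(s$wavelengths[keep], s$values[keep])
}

#' Standard normal variate scaling
#'
#' Centers and scales the reflectance vector to zero mean and unit sample
#' standard deviation (n - 1 denominator), removing multiplicative and
#' additive scatter differences between samples.
#'
#' @param s a [spectrum()].
#' @return A [spectrum()].
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  sdv <- stats::sd(s$values)
  if (!is.finite(sdv) || sdv == 0)
    stop("SNV undefined for a constant spectrum")
  spectrum(s$wavelengths, (s$values - mean(s$values)) / sdv)
}

#' Multiplicative scatter correction
#'
#' Regresses the spectrum on a reference spectrum (ordinary least squares
#' with intercept) and returns `(values - intercept) / slope`, aligning the
#' sample's scatter baseline and amplification to the reference.
#'
#' @param s a [spectrum()].
#' @param reference reference [spectrum()] on the same wavelength axis
#'   (typically the mean calibration spectrum).
#' @return A [spectrum()].
#' @export
msc <- function(s, reference) {
  stopifnot(inherits(s, "spectrum"), inherits(reference, "spectrum"))
  if (!isTRUE(all.equal(s$wavelengths, reference$wavelengths)))
    stop("reference must share the spectrum's wavelength axis")
  fit <- stats::lm.fit(cbind(1, reference$values), s$values)
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps)
    stop("MSC slope is zero; reference carries no signal")
  spectrum(s$wavelengths, (s$values - fit$coefficients[1]) / slope)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()].
#'
#' @param s a [spectrum()].
#' @param window odd filter length, greater than `polyorder`.
#' @param polyorder polynomial order (default 2).
#' @return A [spectrum()].
#' @export
savgol <- function(s, window = 11, polyorder = 2) {
  stopifnot(inherits(s, "spectrum"))
  if (window %% 2 != 1 || window <= polyorder)
    stop("window must be odd and greater than polyorder")
  spectrum(s$wavelengths,
           signal::sgolayfilt(s$values, p = polyorder, n = window))
}

#' Apply a spectral preprocessing chain to the rows of a matrix
#'
#' Convenience used by the pipeline: each row of `X` is treated as a
#' spectrum on `wavelengths` and passed through the named steps in order.
#'
#' @param X samples x bands matrix.
#' @param wavelengths wavelength axis (nm).
#' @param steps character vector among `"wavelet_denoise"`,
#'   `"wavelet_debaseline"`, `"snv"`, `"msc"`, `"savgol"`, `"none"`.
#' @param savgol_window,savgol_polyorder Savitzky-Golay settings.
#' @return Matrix of the same shape (MSC uses the column-mean spectrum of
#'   `X` as reference).
#' @export
preprocess_matrix <- function(X, wavelengths,
                              steps = "wavelet_denoise",
                              savgol_window = 11, savgol_polyorder = 2) {
  X <- as.matrix(X)
  ref <- spectrum(wavelengths, colMeans(X))
  for (step in steps) {
    if (step == "none") next
    X <- t(apply(X, 1, function(v) {
      s <- spectrum(wavelengths, v)
      out <- switch(step,
        wavelet_denoise = wavelet_detrend(s, mode = "denoise"),
        wavelet_debaseline = wavelet_detrend(s, mode = "debaseline"),
        snv = snv(s),
        msc = msc(s, ref),
        savgol = savgol(s, savgol_window, savgol_polyorder),
        stop("unknown preprocessing step: ", step))
      out$values
    }))
  }
  colnames(X) <- sprintf("%.2f", wavelengths)
  X
}
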