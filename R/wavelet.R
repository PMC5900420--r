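# Daubechies-6 decimated wavelet transform with symmetric signal extension.
#
# The scaling (low-pass) filter below is the standard 12-tap db6 filter;
# the high-pass analysis filter and both synthesis filters follow from the
# usual quadrature-mirror relations. Symmetric (edge-repeating) extension
# is used on both ends so that short reflectance spectra can be decomposed
# without periodization artefacts; coefficients therefore depend on this
# extension convention, which is fixed and not user-configurable.

DB6_DEC_LO <- c(
  -0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613,
  -0.03158203931748603, 0.027522865530305727, 0.097501605587323043,
  -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
  0.75113390802109536, 0.49462389039845306, 0.11154074335010947)

wt_filters <- function(wavelet_name = "db6") {
  if (!identical(wavelet_name, "db6"))
    stop("only the 'db6' wavelet is provided")
  lo <- DB6_DEC_LO
  f <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(f))     # QMF partner
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       len = f)
}

# full linear convolution (direct; signals here are short)
conv_full <- function(x, f) {
  n <- length(x); m <- length(f)
  out <- numeric(n + m - 1)
  for (j in seq_len(m)) {
    idx <- j:(j + n - 1)
    out[idx] <- out[idx] + f[j] * x
  }
  out
}

# one analysis step: symmetric extension, filter, downsample
dwt_step <- function(x, filt) {
  n <- length(x); f <- filt$len
  if (n < f) stop("signal too short for the db6 filter support")
  ext <- c(rev(x[seq_len(f - 1)]), x, rev(x[(n - f + 2):n]))
  keep <- (n + f - 1) %/% 2
  a_full <- conv_full(ext, filt$dec_lo)
  d_full <- conv_full(ext, filt$dec_hi)
  idx <- seq(f + 1, by = 2, length.out = keep)
  list(a = a_full[idx], d = d_full[idx])
}

# one synthesis step back to length n
idwt_step <- function(a, d, n, filt) {
  up <- function(c) { u <- numeric(2 * length(c)); u[seq(1, 2 * length(c), 2)] <- c; u }
  rec <- conv_full(up(a), filt$rec_lo) + conv_full(up(d), filt$rec_hi)
  f <- filt$len
  rec[(f - 1):(f - 2 + n)]
}

# multi-level analysis; returns approximation, details (finest first) and
# the per-level lengths needed for exact reconstruction
wt_decompose <- function(x, level, wavelet_name = "db6") {
  filt <- wt_filters(wavelet_name)
  if (level < 1) stop("level must be >= 1")
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    lengths[l] <- length(a)
    s <- dwt_step(a, filt)
    details[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, lengths = lengths,
       wavelet = wavelet_name)
}

wt_reconstruct <- function(dec) {
  filt <- wt_filters(dec$wavelet)
  a <- dec$approx
  for (l in rev(seq_along(dec$details)))
    a <- idwt_step(a, dec$details[[l]], dec$lengths[l], filt)
  a
}

#' Wavelet denoising / baseline removal of a spectrum
#'
#' Decomposes the reflectance vector with a Daubechies-6 wavelet at the
#' requested depth (default 3) under symmetric signal extension, then
#' either (a) `mode = "denoise"`: soft-thresholds every detail level at the
#' universal threshold sigma * sqrt(2 log n), with sigma estimated as the
#' median absolute deviation of the finest-level details divided by 0.6745,
#' and reconstructs; or (b) `mode = "debaseline"`: reconstructs the
#' approximation alone (details zeroed) and subtracts it, leaving the
#' detrended signal. Output length always equals input length and the
#' wavelength axis is untouched.
#'
#' @param s a [spectrum()].
#' @param wavelet_name wavelet identifier; only `"db6"` is provided.
#' @param level decomposition depth (default 3).
#' @param mode `"denoise"` or `"debaseline"`.
#' @return A [spectrum()] on the same wavelength axis.
#' @export
#' @examples
#' lib <- spectral_library(1)
#' s <- simulate_spectrum(lib, pigment = 1, water = 1, noise_sd = 0.01, seed = 1)
#' sd(wavelet_detrend(s)$values - s$values) < 0.01
wavelet_detrend <- function(s, wavelet_name = "db6", level = 3,
                            mode = c("denoise", "debaseline")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "spectrum"))
  x <- s$values
  n <- length(x)
  filt <- wt_filters(wavelet_name)
  if (n < filt$len * 2^(level - 1))
    stop(sprintf("spectrum of length %d too short for level %d", n, level))
  dec <- wt_decompose(x, level, wavelet_name)
  if (mode == "denoise") {
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(n))
    dec$details <- lapply(dec$details, function(d)
      sign(d) * pmax(abs(d) - thr, 0))
    out <- wt_reconstruct(dec)
  } else {
    dec$details <- lapply(dec$details, function(d) numeric(length(d)))
    baseline <- wt_reconstruct(dec)
    out <- x - baseline
  }
  spectrum(s$wavelengths, out)
}
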