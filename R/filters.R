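#' Zero-phase FIR bandpass front end
#'
#' Windowed-sinc (Hamming) FIR bandpass applied forward and backward
#' (zero phase). The default order scales with the low cutoff so the
#' transition band stays below it; the Hamming design gives >= 50 dB
#' stopband attenuation per pass.
#'
#' @param rec an [eeg_recording()] or channels x samples matrix.
#' @param lo,hi band edges in Hz (defaults 1-45); must satisfy
#'   `0 < lo < hi < fs/2`.
#' @param fs_hz sampling rate (taken from the recording if supplied).
#' @param order filter order (even); default `ceiling(3.3 * fs / lo)`
#'   rounded up to even, capped for short inputs.
#' @return same type as `rec`, filtered.
#' @export
fir_bandpass <- function(rec, lo = 1, hi = 45, fs_hz = NULL, order = NULL) {
  is_rec <- inherits(rec, "eeg_recording")
  x <- if (is_rec) rec$data else rec
  if (is.null(fs_hz)) fs_hz <- if (is_rec) rec$fs_hz else
    stop("fs_hz required for matrix input")
  if (!(0 < lo && lo < hi && hi < fs_hz / 2))
    stop("band must satisfy 0 < lo < hi < fs/2")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (is.null(order)) order <- ceiling(3.3 * fs_hz / lo)
  order <- min(order, floor(ncol(x) / 3) - 2)
  if (order %% 2 == 1) order <- order + 1
  if (order < 8) stop("input too short to filter")
  b <- as.numeric(signal::fir1(order, c(lo, hi) / (fs_hz / 2), type = "pass"))
  # linear-phase taps applied forward and backward (zero phase, |H|^2
  # magnitude response) with reflect padding at the edges
  pass <- function(m) Re(convolve_same_reflect(m, as.complex(b)))
  y <- pass(x)
  y <- pass(y[, ncol(y):1, drop = FALSE])[, ncol(y):1, drop = FALSE]
  if (vec) y <- drop(y)
  if (is_rec) { rec$data <- y; rownames(rec$data) <- rec$labels; rec } else y
}

#' Canonical band scheme with three sub-bands per band
#'
#' Five canonical bands (Delta 1-4, Theta 4-8, Alpha 8-15, Beta 15-30,
#' Gamma 30-45 Hz), each split into low/medium/high sub-bands, giving 15
#' analysis center frequencies roughly one sub-bandwidth apart. The
#' default centers place the Alpha-High, Beta-Low, Beta-Med and
#' Beta-High centers at 13, 16, 21 and 27 Hz; all centers can be
#' overridden as long as each stays strictly inside its parent band.
#'
#' @param centers_hz optional length-15 vector of center frequencies
#'   (ordered Delta-low .. Gamma-high).
#' @param wavelet_cycles Morlet cycle count per center (recycled).
#' @return object of class `band_scheme`: data.frame with columns
#'   `band`, `sub_band`, `band_lo`, `band_hi`, `center_hz`, `cycles`.
#' @export
band_scheme <- function(centers_hz = NULL, wavelet_cycles = 7) {
  bands <- data.frame(
    band = rep(c("Delta", "Theta", "Alpha", "Beta", "Gamma"), each = 3),
    sub_band = rep(c("Low", "Med", "High"), times = 5),
    band_lo = rep(c(1, 4, 8, 15, 30), each = 3),
    band_hi = rep(c(4, 8, 15, 30, 45), each = 3),
    stringsAsFactors = FALSE
  )
  if (is.null(centers_hz))
    centers_hz <- c(1.5, 2.5, 3.5,  4.5, 6, 7.5,  9, 11, 13,
                    16, 21, 27,  32, 37, 42)
  if (length(centers_hz) != 15)
    stop("a band scheme needs exactly 15 center frequencies")
  if (any(centers_hz <= bands$band_lo | centers_hz >= bands$band_hi))
    stop("every center frequency must lie strictly inside its parent band")
  bands$center_hz <- centers_hz
  bands$cycles <- rep_len(wavelet_cycles, 15)
  structure(bands, class = c("band_scheme", "data.frame"))
}

#' Morlet wavelet filter bank
#'
#' One complex Morlet wavelet per center frequency of the scheme: a
#' complex exponential under a Gaussian envelope with time-domain SD
#' `sigma_t = cycles / (2 pi f)`, truncated at +-4 sigma and normalized
#' to unit energy. The spectral FWHM (`2 sqrt(2 log 2) / (2 pi sigma_t)`)
#' is recorded per wavelet. Cycle counts below 3 are rejected as giving
#' unstable phase estimates.
#'
#' @param scheme a [band_scheme()].
#' @param fs_hz sampling rate the kernels are sampled at.
#' @return list of 15 `morlet_wavelet` objects, each with `center_hz`,
#'   `cycles`, `sigma_t_s`, `fwhm_hz`, `fs_hz` and complex `kernel`.
#' @export
morlet_filterbank <- function(scheme = band_scheme(), fs_hz = 250) {
  stopifnot(inherits(scheme, "band_scheme"))
  if (any(scheme$cycles < 3))
    stop("wavelet cycle counts below 3 are rejected (unstable phase)")
  lapply(seq_len(nrow(scheme)), function(i) {
    f <- scheme$center_hz[i]
    cyc <- scheme$cycles[i]
    sigma_t <- cyc / (2 * pi * f)
    half <- ceiling(4 * sigma_t * fs_hz)
    t <- (-half:half) / fs_hz
    w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    structure(list(center_hz = f, cycles = cyc, sigma_t_s = sigma_t,
                   fwhm_hz = 2 * sqrt(2 * log(2)) / (2 * pi * sigma_t),
                   fs_hz = fs_hz, kernel = w),
              class = "morlet_wavelet")
  })
}

#' @export
print.morlet_wavelet <- function(x, ...) {
  cat(sprintf("<morlet_wavelet> %g Hz, %g cycles, FWHM %.2f Hz, %d taps\n",
              x$center_hz, x$cycles, x$fwhm_hz, length(x$kernel)))
  invisible(x)
}

# FFT convolution of every row of (real) x with complex kernel k,
# 'same' alignment with reflect padding at both edges.
convolve_same_reflect <- function(x, k) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x); lk <- length(k); half <- (lk - 1) %/% 2
  if (n < lk) stop("signal shorter than the wavelet kernel")
  pad <- half
  left <- x[, pad:1 + 1, drop = FALSE]     # reflect (exclude edge sample)
  right <- x[, n - (1:pad), drop = FALSE]
  xp <- cbind(left, x, right)
  np <- ncol(xp)
  m <- stats::nextn(np + lk - 1, 2)
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(xp), m - np))))
  K <- stats::fft(c(k, rep(0, m - lk)))
  Y <- t(stats::mvfft(X * K, inverse = TRUE)) / m
  # full convolution index of output sample j (1-based): j + lk - 1 ...
  # central part aligned to original samples: offset = pad + half
  out <- Y[, (pad + 2 * half + 1 - half) + seq_len(n) - 1, drop = FALSE]
  if (vec) drop(out) else out
}

#' Analytic signal via Morlet convolution
#'
#' Convolves each channel with a complex Morlet wavelet (reflect padding
#' at the edges, output aligned to the input samples). The modulus is
#' the instantaneous band-limited amplitude, the argument the
#' instantaneous phase at the wavelet's center frequency.
#'
#' @param rec an [eeg_recording()], channels x samples matrix, or vector.
#' @param wavelet a `morlet_wavelet` from [morlet_filterbank()].
#' @return complex matrix (channels x samples) or vector.
#' @export
analytic_signal <- function(rec, wavelet) {
  stopifnot(inherits(wavelet, "morlet_wavelet"))
  x <- if (inherits(rec, "eeg_recording")) rec$data else rec
  convolve_same_reflect(x, wavelet$kernel)
}
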