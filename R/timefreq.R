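# Time-frequency transforms for feature groups H (Stockwell) and I (wavelet).
# Both are FFT-based and implemented here; their defining properties (the
# Stockwell time-marginal equals the Fourier spectrum; Morlet ridges track
# instantaneous frequency) are asserted in the test suite.

#' Discrete Stockwell transform
#'
#' Frequency-dependent Gaussian-windowed time-frequency representation.
#' For DFT index `k > 0` the row is
#' `S(tau, k) = IFFT_m[ X(m + k) * exp(-2 pi^2 m^2 / k^2) ]`
#' with `X = FFT(x) / n`, which guarantees the defining property that the
#' time average of `S(tau, k)` over `tau` equals the Fourier coefficient
#' `X(k)`.
#'
#' @param x Real numeric vector.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequencies (Hz) at which to evaluate; rounded to the nearest
#'   DFT bin, duplicates dropped, DC excluded.
#' @return List with `s` (complex matrix, frequencies x time), `freqs`
#'   (realized bin frequencies, Hz) and `times` (s).
#' @export
stockwell_transform <- function(x, fs, freqs) {
  n <- length(x)
  kk <- unique(pmax(1L, round(freqs * n / fs)))
  kk <- kk[kk <= floor(n / 2)]
  if (!length(kk)) abort("no usable frequencies below Nyquist.")
  X <- fft(x) / n
  m <- seq(0, n - 1)
  m_alias <- ifelse(m > n / 2, m - n, m)   # signed frequency offsets
  s <- matrix(0i, length(kk), n)
  for (r in seq_along(kk)) {
    k <- kk[r]
    shifted <- X[(m + k) %% n + 1]
    gauss <- exp(-2 * pi^2 * m_alias^2 / k^2)
    s[r, ] <- fft(shifted * gauss, inverse = TRUE)
  }
  list(s = s, freqs = kk * fs / n, times = (m) / fs)
}

#' Stockwell-transform features (feature group H)
#'
#' Evaluates the Stockwell transform over the segment's analysis band (the
#' `band` attribute set by [bandpass()], or `band`) at up to `max_freqs`
#' evenly spaced DFT bins, and summarizes `|S|` per channel by mean, median,
#' minimum, maximum, skewness and standard deviation.
#'
#' @param seg An `eeg_segment`.
#' @param band Optional `(low_hz, high_hz)`; defaults to the segment's band.
#' @param max_freqs Cap on the number of frequency rows (keeps long segments
#'   tractable).
#' @return Named numeric vector of length `6 * n_channels` (126 on the
#'   standard montage).
#' @export
stockwell_features <- function(seg, band = NULL, max_freqs = 50) {
  check_recording(seg)
  band <- band %||% attr(seg, "band") %||% c(0.5, seg$fs / 2 - 1)
  freqs <- band_bin_freqs(band, n_samples(seg), seg$fs, max_freqs)
  out <- apply(seg$data, 1, function(x) {
    st <- stockwell_transform(x, seg$fs, freqs)
    six_spectrum_stats(as.numeric(Mod(st$s)))
  })
  stats_to_named(out, rownames(out), seg$channel_names)
}

# evenly spaced DFT-bin frequencies covering a band
band_bin_freqs <- function(band, n, fs, max_freqs) {
  k_lo <- max(1L, floor(band[1] * n / fs))
  k_hi <- min(floor(n / 2), ceiling(band[2] * n / fs))
  if (k_hi < k_lo) k_hi <- k_lo
  kk <- unique(round(seq(k_lo, k_hi, length.out = min(max_freqs, k_hi - k_lo + 1))))
  kk * fs / n
}

#' Continuous Morlet wavelet transform
#'
#' FFT-based continuous wavelet transform with an analytic Morlet mother
#' wavelet (centre frequency `omega0 = 6` rad/s), evaluated at the given
#' scales. The centre frequency in Hz of scale `a` is
#' `omega0 / (2 pi a)` times the sampling rate.
#'
#' @param x Real numeric vector.
#' @param scales Numeric vector of scales (in samples).
#' @param omega0 Morlet centre frequency (radians).
#' @return Complex matrix, scales x time.
#' @export
morlet_cwt <- function(x, scales, omega0 = 6) {
  n <- length(x)
  X <- fft(x)
  w <- 2 * pi * seq(0, n - 1) / n
  w <- ifelse(w > pi, w - 2 * pi, w)       # angular frequency per sample
  out <- matrix(0i, length(scales), n)
  for (i in seq_along(scales)) {
    a <- scales[i]
    psi_hat <- pi^(-0.25) * sqrt(a) * exp(-(a * w - omega0)^2 / 2) * (w > 0)
    out[i, ] <- fft(X * Conj(psi_hat), inverse = TRUE) / n
  }
  out
}

#' Wavelet-transform features (feature group I)
#'
#' Continuous Morlet wavelet transform per channel at `n_scales`
#' logarithmically spaced scales whose centre frequencies span the segment's
#' analysis band; `|W|^2` is summarized by mean, median, minimum, maximum,
#' skewness and standard deviation.
#'
#' @inheritParams stockwell_features
#' @param n_scales Number of scales.
#' @param omega0 Morlet centre frequency (radians).
#' @return Named numeric vector of length `6 * n_channels` (126 on the
#'   standard montage).
#' @export
wavelet_features <- function(seg, band = NULL, n_scales = 30, omega0 = 6) {
  check_recording(seg)
  band <- band %||% attr(seg, "band") %||% c(0.5, seg$fs / 2 - 1)
  scales <- morlet_scales(band, seg$fs, n_scales, omega0)
  out <- apply(seg$data, 1, function(x) {
    w2 <- Mod(morlet_cwt(x, scales, omega0))^2
    six_spectrum_stats(as.numeric(w2))
  })
  stats_to_named(out, rownames(out), seg$channel_names)
}

# scales (in samples) whose Morlet centre frequencies cover [band1, band2] Hz
morlet_scales <- function(band, fs, n_scales, omega0 = 6) {
  f_centre <- function(a) omega0 / (2 * pi * a) * fs
  a_hi <- omega0 * fs / (2 * pi * band[1])  # large scale = low frequency
  a_lo <- omega0 * fs / (2 * pi * band[2])
  exp(seq(log(a_lo), log(a_hi), length.out = n_scales))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
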