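# Per-channel feature families. Each extractor returns a named numeric
# vector; names are "<channel>_<feature>" so channel-qualified values can be
# regrouped into scalp topologies later.

#' Hjorth parameters (feature group A)
#'
#' Activity (variance), mobility (ratio of the first difference's RMS to the
#' signal's RMS, a normalized mean frequency) and complexity (mobility of the
#' first difference divided by mobility of the signal) per channel.
#' Derivatives are first differences.
#'
#' @param seg An [eeg_recording()] / `eeg_segment`.
#' @return Named numeric vector of length `3 * n_channels` (63 on the
#'   standard montage), ordered channel-major.
#' @export
hjorth_features <- function(seg) {
  check_recording(seg)
  if (n_samples(seg) < 3) abort("need at least 3 samples per channel.")
  out <- apply(seg$data, 1, function(x) {
    v0 <- var(x)
    if (v0 == 0) abort("zero-variance channel: Hjorth parameters undefined.")
    d1 <- diff(x); d2 <- diff(d1)
    v1 <- var(d1)
    if (v1 == 0) abort("zero-variance first difference: mobility undefined.")
    mob <- sqrt(v1 / v0)
    c(activity = v0, mobility = mob, complexity = sqrt(var(d2) / v1) / mob)
  })
  stats_to_named(out, c("activity", "mobility", "complexity"),
                 seg$channel_names)
}

# population (biased) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Statistical parameters (feature group B)
#'
#' Skewness, kurtosis (raw fourth standardized moment, Gaussian = 3), mean,
#' median, minimum and maximum per channel.
#'
#' @inheritParams hjorth_features
#' @return Named numeric vector of length `6 * n_channels` (126 on the
#'   standard montage).
#' @export
statistical_features <- function(seg) {
  check_recording(seg)
  if (n_samples(seg) < 2) abort("need at least 2 samples per channel.")
  d <- seg$data
  m <- rowMeans(d)
  z <- d - m
  s <- sqrt(rowMeans(z^2))
  if (any(s == 0)) abort("zero-variance channel: skewness/kurtosis undefined.")
  z <- z / s
  out <- rbind(
    skewness = rowMeans(z^3),
    kurtosis = rowMeans(z^4),
    mean = m,
    median = apply(d, 1, median),
    min = apply(d, 1, min),
    max = apply(d, 1, max)
  )
  stats_to_named(out, rownames(out), seg$channel_names)
}

#' Linear and nonlinear energy (feature group C)
#'
#' Linear energy is the mean squared amplitude. Nonlinear energy defaults to
#' the mean Teager-Kaiser operator,
#' `(1/(n-2)) * sum_t (x(t)^2 - x(t-1) x(t+1))`, the standard instantaneous
#' amplitude-frequency energy in the seizure literature. A literal
#' `as_printed` mode computes the telescoped difference-of-sums form
#' `(x(2)^2 - x(n)^2)/(n-2)` instead.
#'
#' @inheritParams hjorth_features
#' @param nonlinear Which nonlinear-energy convention to use.
#' @return Named numeric vector of length `2 * n_channels` (42 on the
#'   standard montage).
#' @export
energy_features <- function(seg, nonlinear = c("teager_kaiser", "as_printed")) {
  check_recording(seg)
  nonlinear <- match.arg(nonlinear)
  if (n_samples(seg) < 3) abort("need at least 3 samples per channel.")
  out <- apply(seg$data, 1, function(x) {
    n <- length(x)
    nl <- if (nonlinear == "teager_kaiser") {
      sum(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]) / (n - 2)
    } else {
      (x[2]^2 - x[n]^2) / (n - 2)
    }
    c(linear_energy = mean(x^2), nonlinear_energy = nl)
  })
  stats_to_named(out, rownames(out), seg$channel_names)
}

#' Zero-crossing counts (feature group D)
#'
#' Sign-change count `(1/2) * sum_t |sign(x(t)) - sign(x(t-1))|` of the
#' signal and of its first difference. The raw count matches the printed
#' formula; `normalize = TRUE` divides by the number of sample pairs to give
#' a rate.
#'
#' @inheritParams hjorth_features
#' @param normalize Divide counts by `n - 1`?
#' @return Named numeric vector of length `2 * n_channels` (42 on the
#'   standard montage).
#' @export
zero_crossing_features <- function(seg, normalize = FALSE) {
  check_recording(seg)
  if (n_samples(seg) < 3) abort("need at least 3 samples per channel.")
  zc <- function(x) sum(abs(sign(x[-1]) - sign(x[-length(x)]))) / 2
  out <- apply(seg$data, 1, function(x) {
    v <- c(zcr = zc(x), zcr_diff = zc(diff(x)))
    if (normalize) v <- v / c(length(x) - 1, length(x) - 2)
    v
  })
  stats_to_named(out, rownames(out), seg$channel_names)
}

#' Spectral parameters (feature group G)
#'
#' Discrete Fourier transform per channel; the power spectrum
#' `|X_k|^2 / n` is summarized by its mean, median, minimum, maximum,
#' skewness and standard deviation. With this normalization the power bins
#' sum to the time-domain energy `sum x(t)^2` (Parseval). Only the
#' positive-frequency half (excluding DC) is summarized.
#'
#' @inheritParams hjorth_features
#' @return Named numeric vector of length `6 * n_channels` (126 on the
#'   standard montage).
#' @export
spectral_features <- function(seg) {
  check_recording(seg)
  n <- n_samples(seg)
  if (n < 4) abort("need at least 4 samples per channel.")
  out <- apply(seg$data, 1, function(x) {
    p <- power_spectrum(x)
    p <- p[2:floor(length(x) / 2)]        # positive frequencies, no DC
    six_spectrum_stats(p)
  })
  stats_to_named(out, rownames(out), seg$channel_names)
}

#' Periodogram power spectrum
#'
#' `|X_k|^2 / n` over all `n` DFT bins; with this normalization
#' `sum(power_spectrum(x)) == sum(x^2)` exactly (Parseval's theorem).
#'
#' @param x Numeric vector.
#' @return Numeric vector of length `length(x)`.
#' @export
power_spectrum <- function(x) Mod(fft(x))^2 / length(x)

# mean/median/min/max/skewness/sd summary used by groups G, H, I
six_spectrum_stats <- function(v) {
  m <- mean(v); s <- pop_sd(v)
  sk <- if (s == 0) 0 else mean(((v - m) / s)^3)
  c(mean = m, median = median(v), min = min(v), max = max(v),
    skewness = sk, sd = s)
}

# reshape a stats x channels matrix into a channel-qualified named vector
stats_to_named <- function(mat, stat_names, channel_names) {
  vals <- as.numeric(mat)                 # column-major: channel blocks
  names(vals) <- as.character(outer(stat_names, channel_names,
                                    function(s, ch) paste(ch, s, sep = "_")))
  vals
}
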