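#' Epoch the resting-state period and convert to microvolts
#'
#' Extracts the `[start_s, end_s)` portion of a recording. Amplitudes are
#' multiplied by 1e6 when the input is in volts (`units = "V"`), so
#' downstream stages always see microvolts.
#'
#' @param raw An [eeg_recording()].
#' @param start_s,end_s Epoch boundaries in seconds (defaults 20 and 320,
#'   i.e. a 300-s resting window skipping the first 20 s).
#' @param units Input units, `"uV"` (no scaling) or `"V"` (scaled by 1e6).
#' @return An [eeg_recording()] with `(end_s - start_s) * fs` samples per
#'   channel, in microvolts.
#' @export
epoch_resting <- function(raw, start_s = 20, end_s = 320,
                          units = c("uV", "V")) {
  check_recording(raw)
  units <- match.arg(units)
  if (end_s <= start_s) abort("`end_s` must exceed `start_s`.")
  if (duration_s(raw) < end_s) {
    abort(sprintf(
      "recording lasts %.1f s but the epoch ends at %.1f s", duration_s(raw), end_s))
  }
  i0 <- round(start_s * raw$fs) + 1L
  i1 <- round(end_s * raw$fs)
  out <- raw
  out$data <- raw$data[, i0:i1, drop = FALSE]
  if (units == "V") out$data <- out$data * 1e6
  out
}

#' Re-reference against the mean of a channel subset
#'
#' Subtracts, at every sample, the average of the given reference channels.
#' By default the 11 fronto-central-parietal-occipital channels of
#' [reference_channels_1020()] form the reference, and the subtraction is
#' applied to all channels (`mode = "subset_average_all"`). The alternative
#' reading, re-referencing only the listed channels themselves, is available
#' as `mode = "subset_only"`.
#'
#' @param rec An [eeg_recording()].
#' @param reference_channels Channel names forming the reference.
#' @param mode Which channels receive the subtraction.
#' @return An [eeg_recording()] with unchanged channel count.
#' @export
rereference <- function(rec, reference_channels = reference_channels_1020(),
                        mode = c("subset_average_all", "subset_only")) {
  check_recording(rec)
  mode <- match.arg(mode)
  missing <- setdiff(reference_channels, rec$channel_names)
  if (length(missing)) {
    abort(paste0("reference channel(s) not in recording: ",
                 paste(missing, collapse = ", ")))
  }
  ref <- colMeans(rec$data[reference_channels, , drop = FALSE])
  out <- rec
  if (mode == "subset_average_all") {
    out$data <- sweep(rec$data, 2, ref)
  } else {
    out$data[reference_channels, ] <-
      sweep(rec$data[reference_channels, , drop = FALSE], 2, ref)
  }
  out
}

#' Zero-phase Butterworth bandpass
#'
#' Order-4 Butterworth bandpass applied forward and backward
#' ([signal::filtfilt()]), giving zero phase shift. A direct fourth-order
#' bandpass design can be numerically unstable for bands that are very narrow
#' relative to the sampling rate (at 250 Hz this affects only the lowest
#' 0.1-2 Hz band); the pole moduli of each design are checked, and unstable
#' designs fall back to an equivalent cascade of a high-pass and a low-pass
#' of the same order.
#'
#' @param rec An [eeg_recording()].
#' @param band Length-2 numeric `(low_hz, high_hz)`, `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4).
#' @return A filtered [eeg_recording()] of the same shape.
#' @export
bandpass <- function(rec, band, order = 4) {
  check_recording(rec)
  band <- as.numeric(band)
  if (length(band) != 2 || !(0 < band[1] && band[1] < band[2])) {
    abort("`band` must be (low_hz, high_hz) with 0 < low < high.")
  }
  if (band[2] >= rec$fs / 2) {
    abort(sprintf("band edge %.2f Hz is at or above Nyquist (%.2f Hz)",
                  band[2], rec$fs / 2))
  }
  w <- band / (rec$fs / 2)
  bf <- signal::butter(order, w, type = "pass")
  out <- rec
  if (all(Mod(polyroot(rev(bf$a))) < 1)) {
    out$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  } else {
    hp <- signal::butter(order, w[1], type = "high")
    lp <- signal::butter(order, w[2], type = "low")
    out$data <- t(apply(rec$data, 1, function(x)
      signal::filtfilt(lp, signal::filtfilt(hp, x))))
  }
  rownames(out$data) <- rec$channel_names
  attr(out, "band") <- band
  out
}

#' Per-channel z-scoring
#'
#' Centers and scales every channel to mean 0, standard deviation 1 over the
#' full (filtered) epoch, ahead of segmentation.
#'
#' @param rec An [eeg_recording()].
#' @return A standardized [eeg_recording()].
#' @export
standardize <- function(rec) {
  check_recording(rec)
  sds <- apply(rec$data, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance channel(s): ",
                 paste(rec$channel_names[sds == 0], collapse = ", ")))
  }
  out <- rec
  out$data <- (rec$data - rowMeans(rec$data)) / sds
  attr(out, "band") <- attr(rec, "band")
  out
}

#' Cut the leading temporal segment
#'
#' Takes the first `round(fs * length_s)` samples of every channel. All
#' segments start at the 0-s mark of the (epoched) resting-state data.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param length_s Segment duration in seconds.
#' @return An `eeg_segment` (an [eeg_recording()] carrying `band` and
#'   `length_s` attributes).
#' @export
cut_segment <- function(rec, length_s) {
  check_recording(rec)
  n <- round(rec$fs * length_s)
  if (n > n_samples(rec)) {
    abort(sprintf("segment of %.1f s exceeds the %.1f-s recording",
                  length_s, duration_s(rec)))
  }
  out <- rec
  out$data <- rec$data[, seq_len(n), drop = FALSE]
  attr(out, "band") <- attr(rec, "band")
  attr(out, "length_s") <- length_s
  class(out) <- c("eeg_segment", class(rec))
  out
}

#' The 50-band spectral search grid
#'
#' Two-Hz-wide passbands with low cuts 0.1, 1, 2, ..., 49 Hz: (0.1, 2),
#' (1, 3), (2, 4), ..., (49, 51). The first band is kept 1.9 Hz wide as
#' specified rather than forced to 2 Hz.
#'
#' @return A 50-row tibble with columns `low_hz`, `high_hz`.
#' @export
make_spectral_grid <- function() {
  low <- c(0.1, 1:49)
  tibble(low_hz = low, high_hz = c(2, 1:49 + 2))
}

#' The 39-length temporal search grid
#'
#' Window lengths at 1-s intervals from 1 to 30 s and 30-s intervals from
#' 60 to 300 s.
#'
#' @return Sorted numeric vector of 39 durations in seconds.
#' @export
make_temporal_grid <- function() {
  c(1:30, seq(60, 300, by = 30))
}

#' Run the fixed preprocessing chain for one grid cell
#'
#' Applies, in order: resting epoch, microvolt scaling, subset-average
#' re-referencing, zero-phase bandpass, per-channel standardization, and the
#' leading-segment cut. The first three stages are shared by every grid cell,
#' so [run_strategy()] applies them once per subject and only repeats the
#' band- and window-specific tail.
#'
#' @inheritParams epoch_resting
#' @inheritParams bandpass
#' @inheritParams cut_segment
#' @param reference_channels Passed to [rereference()].
#' @return An `eeg_segment`.
#' @export
preprocess_segment <- function(raw, band, length_s, start_s = 20, end_s = 320,
                               units = c("uV", "V"),
                               reference_channels = reference_channels_1020(),
                               order = 4) {
  raw %>%
    epoch_resting(start_s = start_s, end_s = end_s, units = units) %>%
    rereference(reference_channels = reference_channels) %>%
    bandpass(band = band, order = order) %>%
    standardize() %>%
    cut_segment(length_s = length_s)
}
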