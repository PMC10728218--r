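#' Multichannel EEG recording
#'
#' A light container for a multichannel EEG time series: a channels x samples
#' numeric matrix with a sampling rate and ordered channel names. Amplitudes
#' are in microvolts once preprocessed (see [epoch_resting()]).
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Optional subject identifier.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 100), 4), fs = 100,
#'                      channel_names = c("Fp1", "Fp2", "O1", "O2"))
#' n_samples(rec)
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          subject_id = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    abort("`channel_names` must have one entry per row of `data`.")
  }
  if (anyDuplicated(channel_names)) abort("channel names must be unique.")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording%s: %d channels x %d samples @ %g Hz (%.1f s)>\n",
    if (!is.null(x$subject_id)) paste0(" ", x$subject_id) else "",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' @rdname eeg_recording
#' @param x An `eeg_recording`.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname eeg_recording
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_recording
#' @export
duration_s <- function(x) ncol(x$data) / x$fs

#' Standard 21-channel montage and reference subset
#'
#' The 21 electrodes of the modified international 10-20 placement used
#' throughout the package, and the 11 central/parietal/occipital channels used
#' to build the average reference.
#'
#' @return Character vector of channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "T1", "F7", "F3", "Fz", "F4", "F8", "T2", "T3",
    "C3", "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' @rdname montage_1020
#' @export
reference_channels_1020 <- function() {
  c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4", "O1", "O2")
}

# internal: stop with a message if recording is malformed
check_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) abort("expected an `eeg_recording`.")
  if (!all(is.finite(rec$data))) abort("recording contains non-finite samples.")
  invisible(rec)
}
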