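#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: 16-bit samples, one-second data
#' records, physical units in microvolts with a symmetric physical range per
#' file. The physical range is the smallest integer number of microvolts
#' covering the data, so the quantization step is `phys_max / 32767`.
#' Trailing samples that do not fill a whole one-second record are dropped.
#'
#' @param rec An [eeg_recording()] (amplitudes in microvolts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  check_recording(rec)
  if (rec$fs != round(rec$fs)) abort("EDF writer requires an integer sampling rate.")
  spr <- as.integer(rec$fs)                # samples per 1-s record
  n_rec <- floor(n_samples(rec) / spr)
  if (n_rec < 1) abort("recording shorter than one data record.")
  ns <- n_channels(rec)
  dat <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  pmax_phys <- max(1, ceiling(max(abs(dat))))
  dig <- round(dat / pmax_phys * 32767)
  dig[dig > 32767] <- 32767; dig[dig < -32767] <- -32767

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(if (is.null(rec$subject_id)) "X" else rec$subject_id, 80)
  wr("Startdate 01-JAN-2000", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (ch in rec$channel_names) wr(substr(paste("EEG", ch), 1, 16), 16)
  for (i in seq_len(ns)) wr("", 80)                    # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-pmax_phys, 8)
  for (i in seq_len(ns)) wr(pmax_phys, 8)
  for (i in seq_len(ns)) wr(-32767, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)                    # prefiltering
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Companion reader for [write_edf()]: parses the EDF header, converts 16-bit
#' digital samples back to physical units, and returns an [eeg_recording()].
#' Channel labels have a leading `"EEG "` type prefix stripped.
#'
#' @param path EDF file path.
#' @param channels Optional character vector to select (and order) channels
#'   by name.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                    # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) abort("mixed per-signal sampling rates are not supported.")
  fs <- spr[1] / rec_dur
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmin_ - scale * dmin_
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little")
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    out[, idx] <- matrix(block, nrow = ns, byrow = TRUE)
  }
  out <- out * scale + offset
  rec <- eeg_recording(out, fs = fs, channel_names = labels,
                       subject_id = if (nzchar(subject_id)) subject_id else NULL)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing)) {
      abort(paste0("channels not present in file: ",
                   paste(missing, collapse = ", ")))
    }
    rec$data <- rec$data[channels, , drop = FALSE]
    rec$channel_names <- channels
  }
  rec
}

#' Write a cohort as EDF files plus a label manifest
#'
#' One EDF file per subject (named `<subject_id>.edf`) and a tab-separated
#' `manifest.tsv` mapping `subject_id` to outcome label.
#'
#' @param cohort A `labeled_cohort` from [generate_cohort()].
#' @param directory Output directory (created if absent).
#' @return Tibble with columns `subject_id`, `label`, `file` (the manifest),
#'   invisibly written to `manifest.tsv`.
#' @export
write_cohort_edf <- function(cohort, directory) {
  if (!inherits(cohort, "labeled_cohort")) abort("expected a `labeled_cohort`.")
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) abort(sprintf("cannot create directory '%s'", directory))
  files <- character(length(cohort$recordings))
  for (i in seq_along(cohort$recordings)) {
    files[i] <- file.path(directory,
                          paste0(cohort$subject_ids[i], ".edf"))
    write_edf(cohort$recordings[[i]], files[i])
  }
  manifest <- tibble(
    subject_id = cohort$subject_ids,
    label = as.character(cohort$labels),
    file = basename(files)
  )
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Read a cohort written by [write_cohort_edf()]
#'
#' @param directory Directory holding `manifest.tsv` and the EDF files.
#' @return A `labeled_cohort`.
#' @export
read_cohort_edf <- function(directory) {
  mf <- file.path(directory, "manifest.tsv")
  if (!file.exists(mf)) abort(sprintf("no manifest.tsv in '%s'", directory))
  manifest <- utils::read.table(mf, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  recs <- lapply(file.path(directory, manifest$file), read_edf)
  for (i in seq_along(recs)) recs[[i]]$subject_id <- manifest$subject_id[i]
  structure(
    list(recordings = recs,
         labels = factor(manifest$label, levels = c("SF", "NSF")),
         subject_ids = manifest$subject_id),
    class = "labeled_cohort"
  )
}
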