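# The nine feature groups (A-I) behind one dispatcher, plus cohort-level
# tidy feature tables: one row per subject, one column per named feature.

#' Feature groups
#'
#' The nine feature families: A Hjorth (63 values on the standard montage),
#' B statistical moments (126), C energy (42), D zero crossings (42),
#' E correlation-graph summaries (20), F phase-locking-graph summaries (20),
#' G Fourier spectral statistics (126), H Stockwell statistics (126),
#' I wavelet statistics (126).
#'
#' @return Character vector `c("A", ..., "I")`.
#' @export
feature_groups <- function() LETTERS[1:9]

#' @rdname feature_groups
#' @param group A single group letter.
#' @param n_channels Channel count (21 by default).
#' @return `feature_dim()`: the length of the group's feature vector.
#' @export
feature_dim <- function(group, n_channels = 21) {
  per_channel <- c(A = 3, B = 6, C = 2, D = 2, G = 6, H = 6, I = 6)
  if (group %in% c("E", "F")) return(20L)
  if (!group %in% names(per_channel)) abort("unknown feature group.")
  as.integer(per_channel[[group]] * n_channels)
}

#' Extract one feature group from a segment
#'
#' Dispatches to the group's extractor and returns a tidy one-row-per-feature
#' tibble. Graph groups (E/F) first build the correlation or phase-locking
#' connectivity matrix.
#'
#' @param seg An `eeg_segment` (band-passed, standardized, cut).
#' @param group One of `"A"`..`"I"`.
#' @param ... Passed to the group's extractor.
#' @return Tibble with columns `group`, `feature`, `value`.
#' @export
extract_features <- function(seg, group = "B", ...) {
  v <- feature_vector(seg, group, ...)
  tibble(group = group, feature = names(v), value = unname(v))
}

#' @rdname extract_features
#' @return `feature_vector()`: the named numeric vector itself.
#' @export
feature_vector <- function(seg, group = "B", ...) {
  switch(group,
    A = hjorth_features(seg),
    B = statistical_features(seg),
    C = energy_features(seg, ...),
    D = zero_crossing_features(seg, ...),
    E = graph_features(correlation_matrix(seg), ...),
    F = graph_features(plv_matrix(seg), ...),
    G = spectral_features(seg),
    H = stockwell_features(seg, ...),
    I = wavelet_features(seg, ...),
    abort(sprintf("unknown feature group '%s'", group))
  )
}

#' Cohort feature table for one (band, window) cell
#'
#' Runs the fixed preprocessing chain on every recording and extracts the
#' requested feature group, returning a wide tibble: one row per subject,
#' columns `subject_id`, `label`, then the named features.
#'
#' @param cohort A `labeled_cohort`.
#' @param group Feature group letter.
#' @param band `(low_hz, high_hz)` passband.
#' @param window_s Segment length in seconds.
#' @param ... Passed to [preprocess_segment()].
#' @return A wide tibble of features.
#' @export
cohort_features <- function(cohort, group = "B", band = c(0.1, 51),
                            window_s = 300, ...) {
  rows <- purrr::map2(cohort$recordings, seq_along(cohort$recordings),
    function(rec, i) {
      seg <- preprocess_segment(rec, band = band, length_s = window_s, ...)
      v <- feature_vector(seg, group)
      tibble::as_tibble_row(c(
        list(subject_id = cohort$subject_ids[i],
             label = as.character(cohort$labels[i])),
        as.list(v)))
    })
  dplyr::bind_rows(rows)
}
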