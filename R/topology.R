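# Channel-topology comparison: per-channel group means of a channel-qualified
# feature, compared between groups by cosine similarity and Euclidean
# distance.

#' Per-channel group-mean topology map
#'
#' Averages a channel-qualified feature (e.g. `kurtosis`, stored in columns
#' named `<channel>_<feature>`) over the subjects of one group, giving one
#' value per channel for scalp-pattern comparison.
#'
#' @param features Wide feature tibble from [cohort_features()] (columns
#'   `subject_id`, `label`, `<channel>_<feature>`...).
#' @param feature Base feature name, e.g. `"kurtosis"`.
#' @param group Group label to average over (e.g. `"SF"`).
#' @param label_col Name of the label column.
#' @return A `topology_map`: tibble with columns `channel`, `value`, plus
#'   `feature` and `group` attributes.
#' @export
topology_map <- function(features, feature, group, label_col = "label") {
  rows <- features[[label_col]] == group
  if (!any(rows)) abort(sprintf("no subjects with label '%s'", group))
  cols <- grep(paste0("_", feature, "$"), names(features), value = TRUE)
  if (!length(cols)) {
    abort(sprintf("no channel-qualified columns for feature '%s'", feature))
  }
  out <- tibble(
    channel = sub(paste0("_", feature, "$"), "", cols),
    value = unname(vapply(cols, function(cl) mean(features[[cl]][rows]),
                          numeric(1)))
  )
  structure(out, feature = feature, group = group,
            class = c("topology_map", class(out)))
}

#' Cosine similarity and Euclidean distance between two topology maps
#'
#' `CS = a . b / (||a|| ||b||)` and `ED = ||a - b||` over the per-channel
#' values; the maps must share the same channel order.
#'
#' @param a,b `topology_map`s (or tibbles with `channel` and `value`).
#' @return One-row tibble with `cosine_similarity` and `euclidean_distance`.
#' @export
compare_topologies <- function(a, b) {
  if (!identical(a$channel, b$channel)) {
    abort("topology maps must share the same channel order.")
  }
  va <- a$value; vb <- b$value
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) abort("zero-norm topology map: cosine similarity undefined.")
  tibble(
    cosine_similarity = sum(va * vb) / (na * nb),
    euclidean_distance = sqrt(sum((va - vb)^2))
  )
}

#' Group-comparison statistics for every feature column
#'
#' Runs the Mann-Whitney U test and Cliff's delta on each numeric feature
#' column of a wide feature table, comparing the two outcome groups.
#'
#' @param features Wide feature tibble ([cohort_features()]).
#' @param label_col Label column name.
#' @param groups Length-2 character: which label is `x` and which `y`.
#' @return Tibble with one row per feature: `feature`, `u`, `p_value`,
#'   `cliffs_delta`.
#' @export
feature_group_stats <- function(features, label_col = "label",
                                groups = c("SF", "NSF")) {
  num_cols <- setdiff(names(features)[vapply(features, is.numeric, TRUE)],
                      label_col)
  gx <- features[[label_col]] == groups[1]
  gy <- features[[label_col]] == groups[2]
  if (!any(gx) || !any(gy)) abort("both groups must be present.")
  purrr::map(num_cols, function(cl) {
    mw <- mann_whitney_u(features[[cl]][gx], features[[cl]][gy])
    tibble(feature = cl, u = mw$u, p_value = mw$p_value,
           cliffs_delta = cliffs_delta(features[[cl]][gx],
                                       features[[cl]][gy]))
  }) %>% dplyr::bind_rows()
}
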