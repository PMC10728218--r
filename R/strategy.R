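# The four analysis strategies: which of the spectral-band and
# temporal-window axes are searched, and how the winning cell is selected.

#' Candidate (band, window) cells of a strategy
#'
#' NS evaluates the single fixed cell; OFS searches the bands at the fixed
#' window; OTS the windows at the fixed band; OFTS the full cross of both
#' grids (1950 cells at the default 50 x 39 grids).
#'
#' @param strategy One of `"NS"`, `"OFS"`, `"OTS"`, `"OFTS"`.
#' @param bands Tibble with `low_hz`, `high_hz` (default
#'   [make_spectral_grid()]).
#' @param windows Numeric window lengths in seconds (default
#'   [make_temporal_grid()]).
#' @param fixed_band Band used when the spectral axis is not searched.
#' @param fixed_window_s Window used when the temporal axis is not searched.
#' @return Tibble with columns `band_low`, `band_high`, `window_s`.
#' @export
strategy_cells <- function(strategy = c("OFTS", "OFS", "OTS", "NS"),
                           bands = make_spectral_grid(),
                           windows = make_temporal_grid(),
                           fixed_band = c(0.1, 51), fixed_window_s = 300) {
  strategy <- match.arg(strategy)
  if (nrow(bands) == 0 || length(windows) == 0) abort("empty search grid.")
  b <- switch(strategy,
    NS = , OTS = tibble(low_hz = fixed_band[1], high_hz = fixed_band[2]),
    OFS = , OFTS = bands)
  w <- switch(strategy,
    NS = , OFS = fixed_window_s,
    OTS = , OFTS = windows)
  tidyr::expand_grid(window_s = w, dplyr::rename(b, band_low = "low_hz",
                                                 band_high = "high_hz")) %>%
    dplyr::select("band_low", "band_high", "window_s") %>%
    arrange(.data$band_low, .data$window_s)
}

# Compute per-cell feature matrices for a cohort, sharing work across cells:
# the epoch/re-reference pass runs once per subject, the bandpass +
# standardization once per band, the cut + extraction once per cell.
# Returns a tibble (band_low, band_high, window_s, features = list of
# subject x feature matrices).
cell_feature_cache <- function(cohort, cells, feature_group, start_s = 20,
                               end_s = 320, units = "uV",
                               reference_channels = reference_channels_1020(),
                               order = 4) {
  prep <- lapply(cohort$recordings, function(r) {
    r %>%
      epoch_resting(start_s = start_s, end_s = end_s, units = units) %>%
      rereference(reference_channels = reference_channels)
  })
  bands <- dplyr::distinct(cells, .data$band_low, .data$band_high)
  out <- vector("list", nrow(cells))
  for (bi in seq_len(nrow(bands))) {
    band <- c(bands$band_low[bi], bands$band_high[bi])
    filt <- lapply(prep, function(r)
      standardize(bandpass(r, band = band, order = order)))
    wins <- cells$window_s[cells$band_low == band[1] &
                           cells$band_high == band[2]]
    for (w in wins) {
      feats <- t(vapply(filt, function(r)
        feature_vector(cut_segment(r, w), feature_group),
        numeric(feature_dim(feature_group, n_channels(prep[[1]])))))
      rownames(feats) <- cohort$subject_ids
      idx <- which(cells$band_low == band[1] & cells$band_high == band[2] &
                   cells$window_s == w)
      out[[idx]] <- feats
    }
  }
  dplyr::mutate(cells, features = out)
}

#' Run one analysis strategy end to end
#'
#' Preprocesses the cohort, extracts the chosen feature group for every
#' candidate (band, window) cell of the strategy, and evaluates
#' cross-validated classification.
#'
#' In `selection_mode = "post_hoc"` every cell is scored by k-fold CV (with
#' identical fold assignments, so cells are directly comparable) and the cell
#' with the best mean AUC is reported together with the full per-cell grid.
#' Because every strategy's search space at a given seed is a subset of the
#' OFTS space, post-hoc best AUCs are monotone: OFTS >= OFS, OTS >= NS.
#' In `selection_mode = "nested"` the cell (and, when `hyper_grid` is given,
#' the hyperparameters) are chosen inside each outer-training set by inner-CV
#' AUC, so no outer-test subject influences any selection.
#'
#' @param cohort A `labeled_cohort`.
#' @param strategy `"NS"`, `"OFS"`, `"OTS"` or `"OFTS"`.
#' @param feature_group One of `"A"`..`"I"`.
#' @param classifier A classifier adapter ([classifier_rf()] by default).
#' @param hyper_grid Hyperparameter grid for the inner search (`NULL` = use
#'   adapter defaults, no inner search).
#' @param selection_mode `"post_hoc"` (report the best cell's outer metrics)
#'   or `"nested"` (leakage-safe selection inside outer training folds).
#' @param seed Integer seed (folds and model fits).
#' @param k,inner_k Outer/inner fold counts.
#' @param start_s,end_s,units,reference_channels,order Preprocessing options,
#'   see [preprocess_segment()].
#' @inheritParams strategy_cells
#' @return A `cv_report` with `selected_band`, `selected_window_s` and (in
#'   post-hoc mode) a `grid_results` tibble of per-cell mean metrics.
#' @export
run_strategy <- function(cohort, strategy = c("OFTS", "OFS", "OTS", "NS"),
                         feature_group = "B",
                         classifier = classifier_rf(), hyper_grid = NULL,
                         bands = make_spectral_grid(),
                         windows = make_temporal_grid(),
                         fixed_band = c(0.1, 51), fixed_window_s = 300,
                         selection_mode = c("post_hoc", "nested"),
                         seed = 1, k = 5, inner_k = 3,
                         start_s = 20, end_s = 320, units = "uV",
                         reference_channels = reference_channels_1020(),
                         order = 4) {
  strategy <- match.arg(strategy)
  selection_mode <- match.arg(selection_mode)
  cells <- strategy_cells(strategy, bands, windows, fixed_band, fixed_window_s)
  cache <- cell_feature_cache(cohort, cells, feature_group, start_s, end_s,
                              units, reference_channels, order)
  y <- as.character(cohort$labels)
  folds <- make_folds(y, k = k, seed = seed)
  if (selection_mode == "post_hoc") {
    reports <- purrr::map(cache$features, function(x)
      cv_over_folds(x, y, folds, classifier, hyper_grid, inner_k, seed,
                    threshold = 0.5))
    grid_results <- dplyr::bind_cols(
      dplyr::select(cache, "band_low", "band_high", "window_s"),
      dplyr::bind_rows(purrr::map(reports, function(r)
        dplyr::summarise(r$folds, dplyr::across(
          c("auc", "acc", "f1", "tpr", "tnr", "ppv", "npv"), mean))))
    )
    # primary criterion AUC; exact ties (common at coarse fold sizes) broken
    # by accuracy then F1 before falling back to grid order
    best <- order(-grid_results$auc, -grid_results$acc, -grid_results$f1)[1]
    new_cv_report(reports[[best]], classifier = classifier$name,
                  n = length(y), k = k, seed = seed,
                  selected_band = c(cache$band_low[best], cache$band_high[best]),
                  selected_window_s = cache$window_s[best],
                  strategy = strategy, feature_group = feature_group,
                  grid_results = grid_results)
  } else {
    nested_strategy_cv(cache, y, folds, classifier, hyper_grid, inner_k,
                       seed, strategy, feature_group, k)
  }
}

# nested selection of (cell, params): inner CV on each outer-training set
nested_strategy_cv <- function(cache, y, folds, classifier, hyper_grid,
                               inner_k, seed, strategy, feature_group, k) {
  fold_rows <- vector("list", k)
  scores <- numeric(length(y))
  sel <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    inner_folds <- make_folds(y[!test], k = inner_k,
                              seed = derive_seed(seed, f))
    grid <- if (is.null(hyper_grid)) tibble(.dummy = 1) else hyper_grid
    best <- list(auc = -Inf, cell = NA, params = classifier$default_params)
    for (ci in seq_len(nrow(cache))) {
      x_tr <- cache$features[[ci]][!test, , drop = FALSE]
      for (g in seq_len(nrow(grid))) {
        params <- merge_params(classifier, grid[g, ])
        auc <- mean(vapply(seq_len(inner_k), function(i) {
          it <- inner_folds == i
          m <- classifier$fit(x_tr[!it, , drop = FALSE], y[!test][!it],
                              params, derive_seed(seed, f, ci, g, i))
          compute_metrics(y[!test][it],
                          classifier$predict(m, x_tr[it, , drop = FALSE]),
                          positive = classifier$positive)$auc
        }, numeric(1)))
        if (auc > best$auc) best <- list(auc = auc, cell = ci, params = params)
      }
    }
    x <- cache$features[[best$cell]]
    model <- classifier$fit(x[!test, , drop = FALSE], y[!test], best$params,
                            derive_seed(seed, f, 99))
    p <- classifier$predict(model, x[test, , drop = FALSE])
    scores[test] <- p
    sel[[f]] <- tibble(fold = f, band_low = cache$band_low[best$cell],
                       band_high = cache$band_high[best$cell],
                       window_s = cache$window_s[best$cell])
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble(fold = f, n_test = sum(test)),
      compute_metrics(y[test], p, positive = classifier$positive),
      tibble(params = list(best$params))
    )
  }
  sel <- dplyr::bind_rows(sel)
  modal <- sel %>%
    dplyr::count(.data$band_low, .data$band_high, .data$window_s) %>%
    arrange(dplyr::desc(.data$n)) %>% dplyr::slice(1)
  new_cv_report(
    list(folds = dplyr::bind_rows(fold_rows), scores = scores, labels = y),
    classifier = classifier$name, n = length(y), k = k, seed = seed,
    selected_band = c(modal$band_low, modal$band_high),
    selected_window_s = modal$window_s,
    strategy = strategy, feature_group = feature_group,
    grid_results = sel
  )
}

#' Canonical EEG frequency bands
#'
#' Delta 0.1-4, theta 4-8, alpha 8-12, beta1 12-16, beta2 16-20, beta3 20-30
#' and low gamma 30-50 Hz.
#'
#' @return Tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
canonical_bands <- function() {
  tibble(
    band = c("delta", "theta", "alpha", "beta1", "beta2", "beta3",
             "low_gamma"),
    low_hz = c(0.1, 4, 8, 12, 16, 20, 30),
    high_hz = c(4, 8, 12, 16, 20, 30, 50)
  )
}

#' Per-band classification at a fixed window over the canonical bands
#'
#' Evaluates k-fold classification of one feature group separately in each of
#' the seven canonical bands at a fixed window length.
#'
#' @inheritParams run_strategy
#' @param window_s Fixed window length in seconds.
#' @return Tibble: one row per canonical band with its mean metrics, plus a
#'   `report` list-column of `cv_report`s.
#' @export
canonical_band_report <- function(cohort, feature_group = "B", window_s = 300,
                                  classifier = classifier_rf(),
                                  hyper_grid = NULL, seed = 1, k = 5,
                                  inner_k = 3, ...) {
  cb <- canonical_bands()
  reports <- purrr::map(seq_len(nrow(cb)), function(i) {
    run_strategy(
      cohort, strategy = "NS", feature_group = feature_group,
      classifier = classifier, hyper_grid = hyper_grid,
      fixed_band = c(cb$low_hz[i], cb$high_hz[i]), fixed_window_s = window_s,
      selection_mode = "post_hoc", seed = seed, k = k, inner_k = inner_k, ...)
  })
  dplyr::bind_cols(
    cb,
    dplyr::bind_rows(purrr::map(reports, function(r)
      tidyr::pivot_wider(dplyr::select(r$summary, "metric", "mean"),
                         names_from = "metric", values_from = "mean"))),
    tibble(report = reports)
  )
}
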