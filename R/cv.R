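# Classifier adapters and nested cross-validation.

#' Classifier adapters
#'
#' A classifier adapter is a list with `name`, `fit(x, y, params, seed)`
#' returning a fitted model, `predict(model, x)` returning the probability of
#' the positive class, `default_params`, and `grid` (a tibble of
#' hyperparameter combinations searched by the inner folds). The default is a
#' random forest ([ranger::ranger()], single-threaded and seeded for
#' reproducibility); a linear-discriminant adapter is provided as an
#' alternative plug-in behind the same interface.
#'
#' @param num_trees,max_depth,min_node_size Random-forest defaults
#'   (`max_depth = 0` means unbounded).
#' @param positive Positive-class label.
#' @return An adapter list of class `eegopt_classifier`.
#' @export
classifier_rf <- function(num_trees = 100, max_depth = 0, min_node_size = 1,
                          positive = "NSF") {
  structure(list(
    name = "rf",
    positive = positive,
    default_params = list(num_trees = num_trees, max_depth = max_depth,
                          min_node_size = min_node_size),
    grid = tidyr::expand_grid(num_trees = c(100, 300),
                              max_depth = c(0, 5, 10),
                              min_node_size = c(1, 3)),
    fit = function(x, y, params, seed) {
      ranger::ranger(
        x = as.data.frame(x), y = factor(y), probability = TRUE,
        num.trees = params$num_trees, max.depth = params$max_depth,
        min.node.size = params$min_node_size,
        seed = seed, num.threads = 1
      )
    },
    predict = function(model, x) {
      p <- predict(model, data = as.data.frame(x), num.threads = 1)$predictions
      p[, positive]
    }
  ), class = "eegopt_classifier")
}

#' @rdname classifier_rf
#' @export
classifier_lda <- function(positive = "NSF") {
  structure(list(
    name = "lda",
    positive = positive,
    default_params = list(),
    grid = tibble(.dummy = 1),
    fit = function(x, y, params, seed) {
      if (!requireNamespace("MASS", quietly = TRUE)) {
        abort("the LDA adapter needs the MASS package.")
      }
      x <- as.matrix(x)
      keep <- apply(x, 2, function(v) sd(v) > 0)
      m <- MASS::lda(x[, keep, drop = FALSE], grouping = factor(y))
      list(model = m, keep = keep)
    },
    predict = function(model, x) {
      x <- as.matrix(x)[, model$keep, drop = FALSE]
      p <- predict(model$model, x)$posterior
      p[, positive]
    }
  ), class = "eegopt_classifier")
}

# deterministic per-fit seed below 2^31
derive_seed <- function(seed, ...) {
  extras <- c(...)
  v <- as.numeric(seed) * 7919
  if (length(extras)) v <- v + sum(as.numeric(extras) * 104729 * seq_along(extras))
  as.integer(v %% 2147483647)
}

# split a wide feature tibble into x matrix / y labels / ids
split_xy <- function(data, label_col = "label", id_col = "subject_id") {
  stopifnot(is.data.frame(data))
  meta <- intersect(c(label_col, id_col, "band_low", "band_high", "window_s"),
                    names(data))
  x <- as.matrix(data[, setdiff(names(data), meta), drop = FALSE])
  if (!is.numeric(x)) abort("feature columns must be numeric.")
  list(x = x, y = as.character(data[[label_col]]),
       ids = if (id_col %in% names(data)) data[[id_col]] else seq_len(nrow(data)))
}

#' Nested cross-validated classification of a feature table
#'
#' Outer stratified k-fold at the subject level estimates generalization;
#' when `hyper_grid` is given, inner folds on each outer-training set pick
#' the hyperparameters by inner AUC before the outer-test evaluation
#' (leakage-safe grid search). With `hyper_grid = NULL` the classifier's
#' default parameters are used and no inner search runs.
#'
#' @param data Wide tibble: `subject_id`, `label`, then numeric feature
#'   columns (as produced by [cohort_features()]).
#' @param classifier A [classifier_rf()]-style adapter.
#' @param hyper_grid Tibble of hyperparameter combinations, the adapter's
#'   `grid`, or `NULL` for no search.
#' @param k,inner_k Outer and inner fold counts.
#' @param seed Integer seed controlling fold shuffles and model fits.
#' @param threshold Decision threshold for the thresholded metrics.
#' @param label_col,id_col Column names in `data`.
#' @return A `cv_report`: per-fold metrics, mean/sd summary, and pooled
#'   out-of-fold scores.
#' @export
nested_cv <- function(data, classifier = classifier_rf(), hyper_grid = NULL,
                      k = 5, inner_k = 5, seed = 1, threshold = 0.5,
                      label_col = "label", id_col = "subject_id") {
  sp <- split_xy(data, label_col, id_col)
  folds <- make_folds(sp$y, k = k, seed = seed)
  res <- cv_over_folds(sp$x, sp$y, folds, classifier, hyper_grid,
                       inner_k, seed, threshold)
  new_cv_report(res, classifier = classifier$name,
                n = length(sp$y), k = k, seed = seed)
}

# run outer folds given a fold assignment; returns list(folds=tibble, scores)
cv_over_folds <- function(x, y, folds, classifier, hyper_grid, inner_k,
                          seed, threshold) {
  k <- max(folds)
  fold_rows <- vector("list", k)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- folds == f
    params <- select_params(x[!test, , drop = FALSE], y[!test], classifier,
                            hyper_grid, inner_k, derive_seed(seed, f))
    model <- classifier$fit(x[!test, , drop = FALSE], y[!test], params,
                            derive_seed(seed, f, 99))
    p <- classifier$predict(model, x[test, , drop = FALSE])
    scores[test] <- p
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble(fold = f, n_test = sum(test)),
      compute_metrics(y[test], p, threshold = threshold,
                      positive = classifier$positive),
      tibble(params = list(params))
    )
  }
  list(folds = dplyr::bind_rows(fold_rows), scores = scores, labels = y)
}

# inner grid search by mean inner-fold AUC; NULL grid -> adapter defaults
select_params <- function(x, y, classifier, hyper_grid, inner_k, seed) {
  if (is.null(hyper_grid)) return(classifier$default_params)
  if (nrow(hyper_grid) == 1) return(merge_params(classifier, hyper_grid[1, ]))
  inner_folds <- make_folds(y, k = inner_k, seed = seed)
  aucs <- vapply(seq_len(nrow(hyper_grid)), function(g) {
    params <- merge_params(classifier, hyper_grid[g, ])
    mean(vapply(seq_len(inner_k), function(f) {
      test <- inner_folds == f
      m <- classifier$fit(x[!test, , drop = FALSE], y[!test], params,
                          derive_seed(seed, g, f))
      compute_metrics(y[test], classifier$predict(m, x[test, , drop = FALSE]),
                      positive = classifier$positive)$auc
    }, numeric(1)))
  }, numeric(1))
  merge_params(classifier, hyper_grid[which.max(aucs), ])
}

merge_params <- function(classifier, row) {
  params <- classifier$default_params
  for (nm in setdiff(names(row), ".dummy")) params[[nm]] <- row[[nm]]
  params
}

new_cv_report <- function(res, ..., selected_band = NULL,
                          selected_window_s = NULL, strategy = NULL,
                          feature_group = NULL, grid_results = NULL) {
  metric_cols <- c("auc", "acc", "f1", "tpr", "tnr", "ppv", "npv")
  summary <- tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(res$folds[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) sd(res$folds[[m]]), numeric(1))
  )
  structure(
    c(list(folds = res$folds, summary = summary, scores = res$scores,
           labels = res$labels, strategy = strategy,
           feature_group = feature_group, selected_band = selected_band,
           selected_window_s = selected_window_s,
           grid_results = grid_results),
      list(...)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  hdr <- sprintf("<cv_report: %d-fold%s%s>",
                 max(x$folds$fold),
                 if (!is.null(x$strategy)) paste0(", ", x$strategy) else "",
                 if (!is.null(x$feature_group))
                   paste0(", group ", x$feature_group) else "")
  cat(hdr, "\n")
  if (!is.null(x$selected_band)) {
    cat(sprintf("  selected band %.1f-%.1f Hz, window %g s\n",
                x$selected_band[1], x$selected_band[2], x$selected_window_s))
  }
  s <- x$summary
  cat(paste(sprintf("  %s %.3f +/- %.3f", s$metric, s$mean, s$sd),
            collapse = "\n"), "\n")
  invisible(x)
}
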