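# broom-style tidiers and ggplot2 autoplot methods for fitted results.

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One row per outer fold with the seven classification metrics.
#' @export
#' @method tidy cv_report
tidy.cv_report <- function(x, ...) {
  dplyr::select(x$folds, -dplyr::any_of("params"))
}

#' @rdname tidy.cv_report
#' @return `glance()`: a one-row summary (mean AUC/ACC/... with SDs, the
#'   selected band and window, strategy and classifier).
#' @export
#' @method glance cv_report
glance.cv_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(x$summary, c("mean", "sd"), names_to = "stat"),
    names_from = c("metric", "stat"), values_from = "value")
  dplyr::bind_cols(
    tibble(
      strategy = x$strategy %||% NA_character_,
      feature_group = x$feature_group %||% NA_character_,
      classifier = x$classifier %||% NA_character_,
      band_low = if (is.null(x$selected_band)) NA_real_ else x$selected_band[1],
      band_high = if (is.null(x$selected_band)) NA_real_ else x$selected_band[2],
      window_s = x$selected_window_s %||% NA_real_,
      n = x$n
    ),
    wide
  )
}

#' Plot per-fold metrics of a cross-validation report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot: metric means with fold-level points.
#' @export
#' @method autoplot cv_report
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("auc", "acc", "f1", "tpr", "tnr", "ppv", "npv"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = paste(object$strategy %||% "cv",
                                object$feature_group %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a topology map as a labelled channel strip
#'
#' @param object A `topology_map`.
#' @param ... Unused.
#' @return A ggplot of per-channel values.
#' @export
#' @method autoplot topology_map
autoplot.topology_map <- function(object, ...) {
  df <- tibble(channel = factor(object$channel, levels = object$channel),
               value = object$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = attr(object, "feature"),
                  title = paste("group", attr(object, "group"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the per-cell AUC surface of a post-hoc grid search
#'
#' @param report A `cv_report` from [run_strategy()] in post-hoc mode.
#' @return A ggplot tile map of mean AUC over (band, window) cells.
#' @export
plot_strategy_grid <- function(report) {
  gr <- report$grid_results
  if (is.null(gr) || !"auc" %in% names(gr)) {
    abort("report carries no per-cell grid results (post_hoc mode only).")
  }
  ggplot2::ggplot(gr, ggplot2::aes(x = .data$window_s, y = .data$band_low,
                                   fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "window length (s)", y = "band low cut (Hz)",
                  fill = "AUC") +
    ggplot2::theme_minimal()
}
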