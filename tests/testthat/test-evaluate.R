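# Metrics, folds, nested CV and the four analysis strategies.

test_that("AUC matches brute-force pair counting and handles ties", {
  m <- compute_metrics(c(1, 1, 0, 0), c(.9, .4, .6, .1))
  expect_equal(m$auc, 0.75)            # 3 of 4 positive-negative pairs won
  expect_equal(compute_metrics(c(1, 1, 0, 0), c(.9, .8, .2, .1))$auc, 1)
  expect_equal(compute_metrics(c(1, 1, 0, 0), rep(.5, 4))$auc, 0.5)
  # random check against explicit pair enumeration
  set.seed(1)
  for (i in 1:10) {
    y <- rep(c(1, 0), c(6, 5))
    s <- sample(seq(0, 1, by = .1), 11, replace = TRUE)
    pairs <- oracle_pairs(s[y == 1], s[y == 0])
    expect_equal(compute_metrics(y, s)$auc, pairs$u / (6 * 5))
  }
  expect_error(compute_metrics(c(1, 1), c(.2, .3)), "two classes")
})

test_that("thresholded metrics are confusion-matrix identities", {
  y <- c("NSF", "NSF", "NSF", "SF", "SF")
  s <- c(.9, .6, .2, .7, .1)
  m <- compute_metrics(y, s)       # positive NSF, threshold .5
  expect_equal(m$tpr, 2 / 3)
  expect_equal(m$tnr, 1 / 2)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 1 / 2)
  expect_equal(m$acc, 3 / 5)
  expect_equal(m$f1, 2 / 3)
})

test_that("stratified folds for 22/24 give test sizes 9,9,9,9,10", {
  y <- rep(c("SF", "NSF"), c(22, 24))
  for (seed in 1:5) {
    f <- make_folds(y, k = 5, seed = seed)
    sizes <- sort(as.integer(table(f)))
    expect_equal(sizes, c(9, 9, 9, 9, 10))
    # stratification: both classes in every fold
    expect_true(all(table(f, y) >= 4))
  }
})

test_that("nested_cv is deterministic and robust to duplicated columns", {
  set.seed(2)
  n <- 20
  X <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  dat <- dplyr::bind_cols(
    tibble::tibble(subject_id = paste0("s", 1:n),
                   label = rep(c("SF", "NSF"), each = n / 2)),
    tibble::as_tibble(X))
  r1 <- nested_cv(dat, classifier = classifier_rf(num_trees = 50), seed = 5)
  r2 <- nested_cv(dat, classifier = classifier_rf(num_trees = 50), seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  expect_equal(nrow(tidy(r1)), 5)
  expect_true(all(tidy(r1)$auc >= 0 & tidy(r1)$auc <= 1))
  dat_dup <- dplyr::bind_cols(dat, dplyr::rename_with(dat[, -(1:2)],
                                                      ~paste0(.x, "_copy")))
  r3 <- nested_cv(dat_dup, classifier = classifier_rf(num_trees = 50), seed = 5)
  expect_equal(nrow(tidy(r3)), 5)
})

test_that("inner grid search stays deterministic and selects from the grid", {
  set.seed(3)
  n <- 16
  dat <- dplyr::bind_cols(
    tibble::tibble(subject_id = paste0("s", 1:n),
                   label = rep(c("SF", "NSF"), n / 2)),
    tibble::as_tibble(matrix(rnorm(n * 6), n,
                             dimnames = list(NULL, paste0("f", 1:6)))))
  grid <- tibble::tibble(num_trees = c(30, 60))
  r <- nested_cv(dat, classifier = classifier_rf(), hyper_grid = grid,
                 k = 4, inner_k = 2, seed = 9)
  chosen <- vapply(r$folds$params, function(p) p$num_trees, numeric(1))
  expect_true(all(chosen %in% c(30, 60)))
})

test_that("strategy cells enumerate the advertised search spaces", {
  expect_equal(nrow(strategy_cells("OFTS")), 50 * 39)
  expect_equal(nrow(strategy_cells("OFS")), 50)
  expect_equal(nrow(strategy_cells("OTS")), 39)
  cells_ns <- strategy_cells("NS")
  expect_equal(nrow(cells_ns), 1)
  expect_equal(unlist(cells_ns), c(band_low = 0.1, band_high = 51,
                                   window_s = 300))
  expect_error(strategy_cells("OFS", bands = make_spectral_grid()[0, ]),
               "empty")
})

test_that("post-hoc search dominance: OFTS >= OFS, OTS >= NS at a fixed seed", {
  co <- tiny_cohort(n_sf = 4, n_nsf = 4, seed = 21, effect_band = c(30, 32),
                    amp_nsf = 100, rate_nsf = 10)
  bands <- tibble::tibble(low_hz = c(10, 30), high_hz = c(12, 32))
  wins <- c(20, 60)
  run <- function(strategy) {
    run_strategy(co, strategy, feature_group = "B",
                 classifier = classifier_rf(num_trees = 50),
                 bands = bands, windows = wins,
                 fixed_band = c(0.1, 45), fixed_window_s = 60,
                 seed = 31, k = 4, selection_mode = "post_hoc")
  }
  r <- lapply(c(OFTS = "OFTS", OFS = "OFS", OTS = "OTS", NS = "NS"), run)
  auc <- vapply(r, function(x)
    x$summary$mean[x$summary$metric == "auc"], numeric(1))
  expect_gte(auc[["OFTS"]], auc[["OFS"]])
  expect_gte(auc[["OFTS"]], auc[["OTS"]])
  expect_gte(auc[["OFTS"]], auc[["NS"]])
  expect_equal(nrow(r$OFTS$grid_results), 4)
  # with a strong 30-32 Hz effect, the 30-32 cells beat the 10-12 cells
  gr <- r$OFTS$grid_results
  expect_gte(max(gr$auc[gr$band_low == 30]), max(gr$auc[gr$band_low == 10]))
})

test_that("nested selection never trains on outer-test subjects", {
  co <- tiny_cohort(n_sf = 4, n_nsf = 4, seed = 22)
  seen <- new.env(); seen$sets <- list()
  spy <- structure(list(
    name = "spy", positive = "NSF",
    default_params = list(),
    grid = tibble::tibble(.dummy = 1),
    fit = function(x, y, params, seed) {
      seen$sets <- c(seen$sets, list(rownames(x)))
      colMeans(x)
    },
    predict = function(model, x) {
      stats::plogis(rowMeans(x) - mean(model))
    }
  ), class = "eegopt_classifier")
  r <- run_strategy(co, "OFS", feature_group = "B",
                    classifier = spy,
                    bands = tibble::tibble(low_hz = c(10, 30),
                                           high_hz = c(12, 32)),
                    fixed_window_s = 30, seed = 13, k = 2, inner_k = 2,
                    selection_mode = "nested")
  folds <- make_folds(as.character(co$labels), k = 2, seed = 13)
  test_sets <- split(co$subject_ids, folds)
  for (s in seen$sets) {
    disjoint_from_some_test <- any(vapply(test_sets, function(ts)
      length(intersect(s, ts)) == 0, logical(1)))
    expect_true(disjoint_from_some_test)
  }
  expect_equal(nrow(tidy(r)), 2)
})

test_that("canonical bands are the seven published ranges", {
  cb <- canonical_bands()
  expect_equal(nrow(cb), 7)
  expect_equal(cb$low_hz, c(0.1, 4, 8, 12, 16, 20, 30))
  expect_equal(cb$high_hz, c(4, 8, 12, 16, 20, 30, 50))
  expect_equal(cb$band[c(1, 7)], c("delta", "low_gamma"))
})

test_that("glance/tidy/autoplot work on strategy reports", {
  co <- tiny_cohort(n_sf = 3, n_nsf = 3, seed = 23)
  r <- run_strategy(co, "NS", feature_group = "B",
                    classifier = classifier_rf(num_trees = 50),
                    fixed_band = c(25, 35), fixed_window_s = 30,
                    seed = 3, k = 3)
  g <- glance(r)
  expect_equal(g$strategy, "NS")
  expect_true(all(c("auc_mean", "auc_sd", "acc_mean") %in% names(g)))
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(plot_strategy_grid(r), "ggplot")
})
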