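#' Binary classification metrics
#'
#' AUC by the rank statistic (tied scores receive half credit), plus
#' accuracy, F1, sensitivity (TPR), specificity (TNR), positive and negative
#' predictive value at a probability threshold.
#'
#' @param labels Vector of class labels containing both classes.
#' @param scores Predicted probability of the positive class.
#' @param threshold Decision threshold on `scores` (default 0.5).
#' @param positive Which label is the positive class. Defaults to `"NSF"`
#'   when present, otherwise the last of the sorted unique labels (so `1`
#'   for 0/1 labels).
#' @return One-row tibble with columns `auc`, `acc`, `f1`, `tpr`, `tnr`,
#'   `ppv`, `npv`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
compute_metrics <- function(labels, scores, threshold = 0.5,
                            positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("labels must contain exactly two classes.")
  if (is.null(positive)) positive <- if ("NSF" %in% classes) "NSF" else classes[2]
  if (!positive %in% classes) abort("`positive` not found in labels.")
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(scores)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- scores >= threshold
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  safe <- function(num, den) if (den == 0) 0 else num / den
  tpr <- safe(tp, tp + fn); ppv <- safe(tp, tp + fp)
  tibble(
    auc = auc,
    acc = (tp + tn) / length(y),
    f1 = safe(2 * ppv * tpr, ppv + tpr),
    tpr = tpr,
    tnr = safe(tn, tn + fp),
    ppv = ppv,
    npv = safe(tn, tn + fn)
  )
}

#' Stratified k-fold assignment with balanced fold totals
#'
#' Subjects are assigned to folds class by class; each class's members are
#' shuffled and spread so that per-class counts differ by at most one, and
#' the classes' remainders are placed on the folds with the smallest running
#' totals. For a 22/24 split into 5 folds the test-fold sizes are therefore
#' 9, 9, 9, 9 and 10.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`, aligned to `labels`.
#' @export
make_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (min(table(labels)) < k) {
    abort("each class needs at least `k` members for stratified folds.")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(n)
  totals <- integer(k)
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    counts <- rep(base, k)
    if (extra > 0) {
      receive <- order(totals, seq_len(k))[seq_len(extra)]
      counts[receive] <- counts[receive] + 1
    }
    fold[idx] <- rep(seq_len(k), counts)
    totals <- totals + counts
  }
  fold
}
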