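## evaluation: precision/recall/F1, AUROC, repeated hold-out protocol and
## paired significance testing.

#' Confusion counts and threshold metrics
#'
#' Precision = TP / (TP + FP), Recall = TP / (TP + FN),
#' F1 = 2PR / (P + R); any metric with a zero denominator is defined as 0.
#' Class 1 ("good" co-mention) is the positive class.
#'
#' @param labels 0/1 vector of gold labels.
#' @param predicted 0/1 vector of predicted classes, same length.
#' @return list with `counts` (TP, FP, FN, TN), `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop_("labels and predictions differ in length")
  }
  if (length(labels) == 0L) stop_("need at least one example")
  labels <- as.integer(labels)
  predicted <- as.integer(predicted)
  tp <- sum(labels == 1L & predicted == 1L)
  fp <- sum(labels == 0L & predicted == 1L)
  fn <- sum(labels == 1L & predicted == 0L)
  tn <- sum(labels == 0L & predicted == 0L)
  p <- if (tp + fp > 0L) tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(counts = list(TP = tp, FP = fp, FN = fn, TN = tn),
       precision = p, recall = r, f1 = f1)
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the probability that a random positive scores above a random
#' negative, ties counted 1/2 -- the Mann-Whitney formulation, exact under
#' ties (equivalent to trapezoidal integration of the ROC curve).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores (higher = more positive).
#' @return AUROC in `[0, 1]`.
#' @export
compute_auroc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop_("labels and scores differ in length")
  }
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_("AUROC requires both classes present")
  }
  r <- rank(scores)  # average ranks under ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Repeated hold-out evaluation
#'
#' The same train/validation/test partition is reused for every repeat;
#' only the model-initialization/sampling seed varies. This matches
#' reporting a mean and SD over 10 differently seeded runs of an identical
#' split. The SD uses the population (n) denominator, matching a single
#' "SD" summary column over the repeats.
#'
#' @param pipeline_factory `function(splits, seed)` returning a list with
#'   `predicted` (0/1) and `scores` (numeric) for `splits$test`.
#' @param splits list with `train`, `validation`, `test`; `test` must carry
#'   labels either as an `encoded_set` or a data.frame with a `label`
#'   column.
#' @param seeds distinct integer seeds, one per repeat (default 1:10).
#' @return a `metrics_report`: list with `per_repeat` (data.frame of seed,
#'   precision, recall, f1, auroc), `mean`, `sd`, `n_repeats`.
#' @export
repeated_holdout <- function(pipeline_factory, splits, seeds = 1:10) {
  if (anyDuplicated(seeds)) stop_("seeds must be distinct")
  test_labels <- splits$test$label  # encoded_set and data.frame both carry it
  rows <- lapply(seeds, function(s) {
    out <- pipeline_factory(splits, s)
    m <- compute_metrics(test_labels, out$predicted)
    auc <- compute_auroc(test_labels, out$scores)
    data.frame(seed = s, precision = m$precision, recall = m$recall,
               f1 = m$f1, auroc = auc)
  })
  per_repeat <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  metrics <- c("precision", "recall", "f1", "auroc")
  structure(list(per_repeat = per_repeat,
                 mean = vapply(per_repeat[metrics], mean, 0),
                 sd = vapply(per_repeat[metrics], pop_sd, 0),
                 n_repeats = length(seeds)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report over %d repeats>\n", x$n_repeats))
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.3f (SD %.3f)\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Paired t-test between two models' per-repeat metrics
#'
#' Two-sided paired t-test on the differences of seed-aligned metric
#' vectors. Degenerate conventions (documented, not errors): all
#' differences exactly zero gives t = 0, p = 1; nonzero differences with
#' zero variance give p = 0.
#'
#' @param x,y equal-length (n >= 2) metric vectors, same seeds in the same
#'   order.
#' @param names optional model names.
#' @return list with `names`, `mean_diff`, `t`, `df`, `p_value`.
#' @export
paired_ttest <- function(x, y, names = c("x", "y")) {
  if (length(x) != length(y)) stop_("metric vectors differ in length")
  if (length(x) < 2L) stop_("paired t-test needs n >= 2")
  d <- x - y
  n <- length(d)
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (md == 0) {
      t <- 0
      p <- 1
    } else {
      t <- sign(md) * Inf
      p <- 0
    }
  } else {
    t <- md / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(names = names, mean_diff = md, t = t, df = n - 1L, p_value = p)
}
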