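# Classification metrics: confusion matrix, accuracy, per-class precision and
# recall, macro-F1, the Wolpaw information transfer rate, and the paired
# significance test used to compare methods across matched repeats.

#' Confusion matrix from true and predicted class indices
#'
#' @param true_labels,pred_labels integer class indices in `1..k`, equal length.
#' @param k number of classes.
#' @return a `k x k` integer matrix; entry `(i, j)` counts trials of true
#'   class `i` predicted as class `j`.
#' @export
confusion <- function(true_labels, pred_labels, k) {
  if (length(true_labels) != length(pred_labels))
    abort_shape("true and predicted label vectors differ in length")
  if (length(true_labels) &&
      (min(true_labels, pred_labels) < 1 || max(true_labels, pred_labels) > k))
    abort_valid(sprintf("labels must lie in 1..%d", k))
  cm <- matrix(0L, k, k)
  for (i in seq_along(true_labels))
    cm[true_labels[i], pred_labels[i]] <- cm[true_labels[i], pred_labels[i]] + 1L
  cm
}

#' Overall accuracy of a confusion matrix
#'
#' The proportion of correctly predicted trials: the diagonal mass over the
#' total. (For more than two classes this equals the one-vs-rest pooled
#' `(TP+TN)/(TP+FP+FN+TN)` only after an affine rescaling; the trace reading
#' is the multiclass convention used throughout.)
#'
#' @param cm confusion matrix from [confusion()].
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) abort_valid("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' One-vs-rest precision and recall for one class
#'
#' Reads TP, FP and FN for class `class_i` from the confusion matrix. A class
#' that is never predicted has precision 0 by convention; a class with no true
#' trials has recall 0.
#'
#' @param cm confusion matrix.
#' @param class_i class index.
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(cm, class_i) {
  tp <- cm[class_i, class_i]
  fp <- sum(cm[, class_i]) - tp
  fn <- sum(cm[class_i, ]) - tp
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of the per-class harmonic mean of precision
#' and recall; a class with precision + recall = 0 contributes F1 = 0.
#'
#' @param cm confusion matrix.
#' @return macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  k <- nrow(cm)
  if (k < 2) abort_valid("macro-F1 needs at least 2 classes")
  f1 <- vapply(seq_len(k), function(i) {
    pr <- precision_recall(cm, i)
    if (sum(pr) == 0) 0 else 2 * pr[["precision"]] * pr[["recall"]] / sum(pr)
  }, 0)
  mean(f1)
}

#' Information transfer rate (Wolpaw formula)
#'
#' `ITR = 60 / T * (log2 r + m log2 m + (1 - m) log2((1 - m) / (r - 1)))`
#' bit/min, with the limits `0 * log2(0) := 0`. Below chance (`m < 1/r`) the
#' formula's symmetric-channel reading is not meaningful and the rate is
#' reported as 0.
#'
#' @param m accuracy in `[0, 1]`.
#' @param r number of classes (>= 2).
#' @param t_select_s single-selection time in seconds (analysis window plus
#'   any gaze-shift time).
#' @return ITR in bit/min.
#' @export
itr <- function(m, r, t_select_s) {
  if (r < 2) abort_valid("ITR needs r >= 2 classes")
  if (m < 0 || m > 1) abort_valid("accuracy m must lie in [0, 1]")
  if (t_select_s <= 0) abort_valid("selection time must be positive")
  if (m <= 1 / r) return(0)
  term_m <- if (m > 0) m * log2(m) else 0
  term_e <- if (m < 1) (1 - m) * log2((1 - m) / (r - 1)) else 0
  bits <- log2(r) + term_m + term_e
  60 / t_select_s * bits
}

#' Full metrics report for one evaluated configuration
#'
#' @param true_labels,pred_labels class indices in `1..k`.
#' @param k number of classes.
#' @param t_select_s selection time for the ITR (seconds).
#' @return list with `confusion`, `accuracy`, `precision` and `recall`
#'   (per-class vectors), `macro_f1`, and `itr_bit_min`.
#' @export
metrics_report <- function(true_labels, pred_labels, k, t_select_s) {
  cm <- confusion(true_labels, pred_labels, k)
  pr <- vapply(seq_len(k), function(i) precision_recall(cm, i), c(precision = 0, recall = 0))
  m <- accuracy(cm)
  list(confusion = cm, accuracy = m,
       precision = pr["precision", ], recall = pr["recall", ],
       macro_f1 = macro_f1(cm), itr_bit_min = itr(m, k, t_select_s))
}

#' Paired significance test over matched repeats
#'
#' Two-sided paired t-test on per-repeat accuracies of two methods evaluated
#' on identical splits. Identical vectors (zero-variance differences) return
#' p = 1 with a warning rather than an error.
#'
#' @param acc_a,acc_b numeric vectors of equal length >= 3, matched by repeat.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"` (tests
#'   whether `acc_a` exceeds / falls below `acc_b`).
#' @return the p-value.
#' @export
paired_test <- function(acc_a, acc_b, alternative = "two.sided") {
  if (length(acc_a) != length(acc_b)) abort_shape("paired vectors differ in length")
  if (length(acc_a) < 3) abort_valid("need at least 3 matched repeats")
  d <- acc_a - acc_b
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    if (abs(mean(d)) <= 1e-12) {
      warning("zero-variance paired differences; p-value set to 1")
      return(1)
    }
    # constant non-zero shift: infinite t statistic in the shift's direction
    if (alternative == "greater") return(if (mean(d) > 0) 0 else 1)
    if (alternative == "less") return(if (mean(d) < 0) 0 else 1)
    return(0)
  }
  stats::t.test(acc_a, acc_b, paired = TRUE, alternative = alternative)$p.value
}
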