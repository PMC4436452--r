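# Multilabel evaluation: Hamming loss, macro-F1 and micro-F1, plus the
# paired t-test used to compare methods across cross-validation cells.
# F1 is defined as 0 whenever its denominator vanishes: with several
# hundred GO terms and a handful of positives per protein, most labels are
# unpredicted and any other convention would inflate macro-F1.

#' Hamming loss
#'
#' Fraction of bag-label cells predicted incorrectly.
#'
#' @param pred,truth Binary matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
hamming_loss <- function(pred, truth) {
  assert_binary_matrix(pred, "pred")
  assert_binary_matrix(truth, "truth")
  assert_same_shape(pred, truth)
  mean(pred != truth)
}

per_label_f1 <- function(pred, truth) {
  tp <- colSums(pred == 1 & truth == 1)
  fp <- colSums(pred == 1 & truth == 0)
  fn <- colSums(pred == 0 & truth == 1)
  denom <- 2 * tp + fp + fn
  ifelse(denom > 0, 2 * tp / denom, 0)
}

#' Macro-averaged F1
#'
#' F1 per label (0 when the label has no predicted and no true positives),
#' averaged over all labels. Sensitive to performance on rare labels.
#'
#' @inheritParams hamming_loss
#' @return Scalar in `[0, 1]`.
#' @export
macro_f1 <- function(pred, truth) {
  assert_binary_matrix(pred, "pred")
  assert_binary_matrix(truth, "truth")
  assert_same_shape(pred, truth)
  mean(per_label_f1(pred, truth))
}

#' Micro-averaged F1
#'
#' F1 on counts pooled over all bags and labels. Dominated by frequent
#' labels.
#'
#' @inheritParams hamming_loss
#' @return Scalar in `[0, 1]`.
#' @export
micro_f1 <- function(pred, truth) {
  assert_binary_matrix(pred, "pred")
  assert_binary_matrix(truth, "truth")
  assert_same_shape(pred, truth)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  denom <- 2 * tp + fp + fn
  if (denom == 0) 0 else 2 * tp / denom
}

#' All three multilabel metrics at once
#'
#' @inheritParams hamming_loss
#' @return List with `hamming_loss`, `macro_f1`, `micro_f1` and
#'   `per_label_f1`.
#' @export
multilabel_metrics <- function(pred, truth) {
  list(hamming_loss = hamming_loss(pred, truth),
       macro_f1 = macro_f1(pred, truth),
       micro_f1 = micro_f1(pred, truth),
       per_label_f1 = per_label_f1(pred, truth))
}

#' Two-sided paired t-test with a degenerate-difference convention
#'
#' Wraps [stats::t.test()] (paired, two-sided). When the differences have
#' zero standard deviation the t statistic is undefined; by convention the
#' result is then p = 1 for a zero mean difference (the samples are
#' identical) and p = 0 for a nonzero constant shift (the shift is
#' certain).
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @param level Confidence level; significance means `p < 1 - level`
#'   (default 0.95).
#' @return List with `t`, `p` and `significant`.
#' @export
paired_t_test <- function(a, b, level = 0.95) {
  if (length(a) != length(b)) stopf("paired samples must have equal length")
  if (length(a) < 2L) stopf("paired t-test needs at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    ht <- stats::t.test(a, b, paired = TRUE)
    t <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(t = t, p = p, significant = p < 1 - level)
}
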