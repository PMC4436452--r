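# Weak-label masking: derive an observed (incomplete) label matrix from a
# full one at a target weak-label ratio (W.L.R.), and measure realized
# ratios. The W.L.R. of label l is ||Yhat[,l]||_1 / ||Y[,l]||_1, the
# per-label fraction of true positives retained. Masking is missing-only:
# an observed 0 means "unknown", never "negative".

#' Mask a full label matrix to a target weak-label ratio
#'
#' Per label column with `p` positives, `max(min_keep, round(ratio * p))`
#' positives are retained uniformly at random (round half to even, capped at
#' `p`); all other entries become 0. Masking is performed per column to match
#' the columnwise W.L.R. definition. `min_keep = 1` guarantees no label
#' vanishes from training (an all-zero column is unlearnable and makes
#' macro-F1 ill-defined).
#'
#' @param x A `miml_dataset` with a full label matrix, or a binary matrix.
#' @param ratio Target weak-label ratio in (0, 1].
#' @param seed Integer seed; masking is bit-reproducible given the seed.
#' @param min_keep Minimum positives retained per column (default 1).
#' @return Same type as `x`: dataset with `role = "observed"`, or matrix.
#' @export
mask_labels <- function(x, ratio, seed, min_keep = 1L) {
  UseMethod("mask_labels")
}

#' @export
mask_labels.miml_dataset <- function(x, ratio, seed, min_keep = 1L) {
  if (x$role != "full") stopf("mask_labels expects a dataset with a full label matrix")
  new_dataset(x$bags, mask_labels(x$Y, ratio, seed, min_keep), "observed")
}

#' @export
mask_labels.matrix <- function(x, ratio, seed, min_keep = 1L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1) {
    stopf("ratio must lie in (0, 1]")
  }
  assert_binary_matrix(x, "Y")
  if (min_keep < 0) stopf("min_keep must be >= 0")
  Yhat <- x
  with_seed(seed, {
    for (l in seq_len(ncol(x))) {
      pos <- which(x[, l] == 1)
      p <- length(pos)
      if (p == 0L) next
      k <- min(p, max(min_keep, round(ratio * p)))
      keep <- if (k == 0L) integer(0) else pos[sample.int(p, k)]
      Yhat[, l] <- 0
      Yhat[keep, l] <- 1
    }
  })
  Yhat
}

#' Realized weak-label ratio of an observed matrix
#'
#' @param Y_hat Observed binary matrix (subset of `Y`'s positives).
#' @param Y Full binary matrix of the same shape.
#' @return List with `per_label` (named ratio per column, `NA` where `Y`'s
#'   column has no positives), `mean` (over defined columns) and `undefined`
#'   (ids of columns with zero positives in `Y`).
#' @export
realized_wlr <- function(Y_hat, Y) {
  assert_binary_matrix(Y_hat, "Y_hat")
  assert_binary_matrix(Y, "Y")
  assert_same_shape(Y_hat, Y)
  if (any(Y_hat > Y)) stopf("Y_hat must be elementwise <= Y (weak labels are missing-only)")
  denom <- colSums(Y)
  ratio <- ifelse(denom > 0, colSums(Y_hat) / denom, NA_real_)
  names(ratio) <- colnames(Y)
  list(per_label = ratio,
       mean = mean(ratio, na.rm = TRUE),
       undefined = colnames(Y)[denom == 0] %||% which(denom == 0))
}
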