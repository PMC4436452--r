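# Bag-level feature map Phi^C: a bag becomes a vector of RBF responses to K
# medoid bags (chosen by Hausdorff k-medoids over the training set) plus a
# bias coordinate. K is a fraction alpha of the training bags and the kernel
# width is the mean nearest-medoid distance scaled by mu — the two tunable
# parameters of the learner.

#' Fit a Hausdorff k-medoids RBF bag embedding
#'
#' `K = max(1, round(alpha * m))` medoid bags are selected by [k_medoids()]
#' under the chosen Hausdorff distance. The base kernel width `delta` is the
#' mean over training bags of the distance to their nearest medoid; if that
#' mean is zero (degenerate data), `delta` falls back to the smallest
#' positive pairwise medoid distance, and to 1 if there is none. A bag `X`
#' embeds as `exp(-d(X, medoid_k)^2 / (2 (mu * delta)^2))` for each medoid,
#' plus a final bias coordinate fixed at 1, so the embedding dimension is
#' `K + 1`.
#'
#' @param bags List of training bags.
#' @param alpha Fraction of training bags used as medoids, in (0, 1]
#'   (default 0.1).
#' @param mu Positive scaling factor for the kernel width (default 1.0).
#' @param seed Integer seed for medoid initialization.
#' @param distance Bag distance: "avg" (default) or "max" Hausdorff.
#' @return An object of class `bag_embedding` with the medoid bags, `delta`,
#'   `mu`, `alpha`, `K` and `distance`.
#' @export
fit_bag_embedding <- function(bags, alpha = 0.1, mu = 1.0, seed = 1L,
                              distance = c("avg", "max")) {
  distance <- match.arg(distance)
  if (!length(bags)) stopf("cannot fit an embedding on an empty bag list")
  if (alpha <= 0 || alpha > 1) stopf("alpha must lie in (0, 1]")
  if (mu <= 0) stopf("mu must be positive")
  m <- length(bags)
  K <- max(1L, as.integer(round(alpha * m)))
  D <- bag_dist_matrix(bags, distance)
  med_idx <- k_medoids(D, K, seed)
  near <- apply(D[, med_idx, drop = FALSE], 1, min)
  delta <- mean(near)
  if (delta == 0) {
    pos <- D[med_idx, med_idx][D[med_idx, med_idx] > 0]
    delta <- if (length(pos)) min(pos) else 1
  }
  structure(list(medoids = bags[med_idx], medoid_idx = med_idx,
                 delta = delta, mu = mu, alpha = alpha, K = K,
                 distance = distance),
            class = "bag_embedding")
}

#' @export
print.bag_embedding <- function(x, ...) {
  cat(sprintf("<bag_embedding> K=%d medoids (+bias), delta=%.4g, mu=%.3g, %s Hausdorff\n",
              x$K, x$delta, x$mu, x$distance))
  invisible(x)
}

#' Embed bags with a fitted bag embedding
#'
#' @param model A [fit_bag_embedding()] result.
#' @param bags List of bags (or a single `miml_bag`).
#' @return Numeric matrix, one row per bag, `K + 1` columns (last column is
#'   the constant bias 1).
#' @export
embed_bags <- function(model, bags) {
  stopifnot(inherits(model, "bag_embedding"))
  if (inherits(bags, "miml_bag")) bags <- list(bags)
  dims <- vapply(bags, bag_dim, integer(1))
  if (any(dims != bag_dim(model$medoids[[1]]))) {
    stopf("instance dimension mismatch with the fitted medoids")
  }
  D <- bag_cross_dist(bags, model$medoids, model$distance)
  phi <- exp(-D^2 / (2 * (model$mu * model$delta)^2))
  cbind(phi, 1)
}
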