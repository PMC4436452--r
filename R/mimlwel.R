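# The MIMLwel learner: per-label linear predictors over the bag embedding,
# coupled across related labels by a squared group-(2,1) penalty, with
# budgeted completion of the observed (weak) label matrix.
#
# Objective, minimized over W (d x L) and the corrected matrix Ybar:
#
#   eta * sum_l sum_i (w_l' phi_i - (2*ybar_il - 1))^2
#     + sum_{related pairs l<l'} ( sum_r sqrt(W[r,l]^2 + W[r,l']^2) )^2
#
# subject to: ybar_il = 1 wherever yhat_il = 1, and per label
# ||Ybar_l - Yhat_l||_1 <= floor(epsilon * ||Yhat_l||_1). The (2,1)-norm
# couples the predictors of related labels row-wise: rows of the stacked
# pair [w_l w_l'] are pushed to zero jointly, encoding the assumption that
# highly relevant labels share common instances. Optimization alternates a
# gradient-descent W-step (on a smoothed row norm) with an exact budgeted
# Ybar-step; both steps descend, so the recorded objective trace is
# non-increasing.

#' Build a label relation matrix from observed label columns
#'
#' Two labels are related (`R = 1`) iff the cosine similarity of their
#' observed label columns reaches `tau`; columns with zero norm are related
#' to nothing. The diagonal is forced to 0 and the matrix is symmetric.
#'
#' @param Y_hat Observed binary label matrix.
#' @param tau Cosine threshold in `[0, 1]` (default 0.5).
#' @return An object of class `relation_matrix`: binary L x L matrix with
#'   attribute `tau`.
#' @export
build_relation_matrix <- function(Y_hat, tau = 0.5) {
  assert_binary_matrix(Y_hat, "Y_hat")
  if (tau < 0 || tau > 1) stopf("tau must lie in [0, 1]")
  nrm <- sqrt(colSums(Y_hat^2))
  G <- crossprod(Y_hat)
  denom <- outer(nrm, nrm)
  cosine <- ifelse(denom > 0, G / denom, 0)
  R <- (cosine >= tau) * 1
  R[denom == 0] <- 0
  diag(R) <- 0
  dimnames(R) <- list(colnames(Y_hat), colnames(Y_hat))
  structure(R, tau = tau, class = c("relation_matrix", class(R)))
}

# Squared smoothed group-(2,1) penalty and its gradient for the related
# pairs; `pairs` is a 2-column index matrix (l < l').
group_penalty <- function(W, pairs, sigma) {
  if (!nrow(pairs)) return(list(value = 0, grad = W * 0))
  val <- 0
  G <- W * 0
  for (p in seq_len(nrow(pairs))) {
    l1 <- pairs[p, 1]; l2 <- pairs[p, 2]
    s <- sqrt(W[, l1]^2 + W[, l2]^2 + sigma^2)
    S <- sum(s)
    val <- val + S^2
    G[, l1] <- G[, l1] + 2 * S * W[, l1] / s
    G[, l2] <- G[, l2] + 2 * S * W[, l2] / s
  }
  list(value = val, grad = G)
}

related_pairs <- function(R) {
  idx <- which(upper.tri(R) & R == 1, arr.ind = TRUE)
  if (!nrow(idx)) matrix(integer(0), 0, 2) else unname(idx)
}

# W-step: minimize the smooth objective for fixed targets T (entries +-1) by
# gradient descent with Barzilai-Borwein step proposals safeguarded by Armijo
# backtracking, until the relative objective change drops below `tol`.
solve_w <- function(Phi, Targets, W0, pairs, eta, tol, max_inner, sigma) {
  obj_grad <- function(W) {
    Res <- Phi %*% W - Targets
    pen <- group_penalty(W, pairs, sigma)
    list(value = eta * sum(Res^2) + pen$value,
         grad = 2 * eta * crossprod(Phi, Res) + pen$grad)
  }
  W <- W0
  og <- obj_grad(W)
  step <- 1 / max(1, sum(Phi^2))
  streak <- 0L  # consecutive near-stationary steps before declaring convergence
  for (it in seq_len(max_inner)) {
    g <- og$grad
    gnorm2 <- sum(g^2)
    if (gnorm2 == 0) break
    accepted <- FALSE
    s <- step
    for (bt in 1:50) {
      W_new <- W - s * g
      og_new <- obj_grad(W_new)
      if (og_new$value <= og$value - 1e-4 * s * gnorm2) { accepted <- TRUE; break }
      s <- s / 2
    }
    if (!accepted) break
    # Barzilai-Borwein proposal for the next step length
    dW <- W_new - W
    dG <- og_new$grad - og$grad
    denom <- sum(dW * dG)
    step <- if (denom > 0) sum(dW^2) / denom else s * 2
    rel <- abs(og$value - og_new$value) / max(abs(og$value), .Machine$double.eps)
    W <- W_new
    og <- og_new
    # a single small BB step can be a plateau, not a solution; require a run
    streak <- if (rel < tol) streak + 1L else 0L
    if (streak >= 3L) break
  }
  list(W = W, value = og$value)
}

#' Fit the MIMLwel model on embedded bags
#'
#' Alternating optimization: the W-step fits all per-label predictors
#' jointly under the group penalty by gradient descent (smoothed row norm,
#' run to a relative objective change below `tol` or `max_inner`
#' iterations); the Ybar-step completes the observed matrix per label within
#' a budget `floor(epsilon * ||Yhat_l||_1)`, flipping only zero entries with
#' the largest positive scores. The outer loop stops when Ybar stops
#' changing or after `max_outer` rounds.
#'
#' @param embeddings m x d matrix of embedded training bags ([embed_bags()]).
#' @param Y_hat m x L observed binary label matrix.
#' @param R Optional [build_relation_matrix()] result (`NULL` = no coupling).
#' @param eta Positive weight of the empirical risk term (default 1.0).
#' @param epsilon Correction budget fraction, `>= 0` (default 0.2); `0`
#'   forces `Ybar == Yhat`.
#' @param max_outer Maximum alternating rounds (default 20).
#' @param tol Relative objective tolerance of the W-step (default 1e-6).
#' @param max_inner Maximum W-step gradient iterations (default 500).
#' @param sigma Row-norm smoothing constant (default 1e-8).
#' @return An object of class `mimlwel_fit`: `W` (d x L), `Y_bar`, `trace`
#'   (objective per outer round, non-increasing) and the settings.
#' @export
fit_mimlwel <- function(embeddings, Y_hat, R = NULL, eta = 1.0, epsilon = 0.2,
                        max_outer = 20L, tol = 1e-6, max_inner = 500L,
                        sigma = 1e-8) {
  Phi <- as.matrix(embeddings)
  if (!all(is.finite(Phi))) stopf("embeddings contain non-finite values")
  assert_binary_matrix(Y_hat, "Y_hat")
  if (nrow(Phi) != nrow(Y_hat)) stopf("embeddings and Y_hat disagree on the number of bags")
  if (eta <= 0) stopf("eta must be positive")
  if (epsilon < 0) stopf("epsilon must be >= 0")
  L <- ncol(Y_hat)
  d <- ncol(Phi)
  if (is.null(R)) R <- matrix(0, L, L)
  if (!identical(dim(unclass(R)), c(L, L))) stopf("R must be L x L")
  pairs <- related_pairs(unclass(R))
  budget <- floor(epsilon * colSums(Y_hat))

  W <- matrix(0, d, L)
  Ybar <- Y_hat
  trace <- numeric(0)
  for (outer in seq_len(max_outer)) {
    fit <- solve_w(Phi, 2 * Ybar - 1, W, pairs, eta, tol, max_inner, sigma)
    W <- fit$W
    scores <- Phi %*% W
    Ybar_new <- Y_hat
    for (l in seq_len(L)) {
      b <- budget[l]
      if (b < 1) next
      cand <- which(Y_hat[, l] == 0 & scores[, l] > 0)
      if (!length(cand)) next
      take <- cand[order(-scores[cand, l], cand)][seq_len(min(b, length(cand)))]
      Ybar_new[take, l] <- 1
    }
    pen <- group_penalty(W, pairs, sigma)
    trace <- c(trace, eta * sum((scores - (2 * Ybar_new - 1))^2) + pen$value)
    if (identical(Ybar_new, Ybar)) break
    Ybar <- Ybar_new
  }
  structure(list(W = W, Y_bar = Ybar, Y_hat = Y_hat, trace = trace,
                 eta = eta, epsilon = epsilon, tau = attr(R, "tau"),
                 relations = R, budget = budget),
            class = "mimlwel_fit")
}

#' @export
print.mimlwel_fit <- function(x, ...) {
  cat(sprintf("<mimlwel_fit> %d labels, d=%d; eta=%.3g, epsilon=%.3g; %d corrected positives; %d outer round(s)\n",
              ncol(x$W), nrow(x$W), x$eta, x$epsilon,
              sum(x$Y_bar) - sum(x$Y_hat), length(x$trace)))
  invisible(x)
}

#' Predict label scores from an embedded test set
#'
#' @param object A `mimlwel_fit`.
#' @param embeddings n x d matrix of embedded bags.
#' @param ... Unused.
#' @return List with `scores` (`Phi W`) and `binary` (`scores > 0`, the
#'   symmetric decision boundary under the +-1 target coding).
#' @export
predict.mimlwel_fit <- function(object, embeddings, ...) {
  Phi <- as.matrix(embeddings)
  if (ncol(Phi) != nrow(object$W)) {
    stopf("embedding dimension %d does not match the fitted model (%d)",
          ncol(Phi), nrow(object$W))
  }
  scores <- Phi %*% object$W
  colnames(scores) <- colnames(object$Y_hat)
  list(scores = scores, binary = (scores > 0) * 1)
}

#' Train MIMLwel end to end from bags and weak labels
#'
#' Convenience wrapper fitting the bag embedding, the label relation matrix
#' and the MIMLwel core in one call; the returned model embeds and scores
#' raw bags directly.
#'
#' @param bags List of training bags.
#' @param Y_hat Observed binary label matrix (rows follow `bags`).
#' @param alpha,mu Embedding parameters (see [fit_bag_embedding()]).
#' @param tau Relation threshold (see [build_relation_matrix()]).
#' @param eta,epsilon,max_outer,tol,max_inner Core parameters (see
#'   [fit_mimlwel()]).
#' @param seed Integer seed for the medoid initialization.
#' @param distance Bag distance for the embedding ("avg" or "max").
#' @return An object of class `mimlwel_model` wrapping the embedding and the
#'   core fit.
#' @export
mimlwel_train <- function(bags, Y_hat, alpha = 0.1, mu = 1.0, tau = 0.5,
                          eta = 1.0, epsilon = 0.2, seed = 1L,
                          max_outer = 20L, tol = 1e-6, max_inner = 500L,
                          distance = "avg") {
  embedding <- fit_bag_embedding(bags, alpha = alpha, mu = mu, seed = seed,
                                 distance = distance)
  Phi <- embed_bags(embedding, bags)
  R <- build_relation_matrix(Y_hat, tau)
  fit <- fit_mimlwel(Phi, Y_hat, R, eta = eta, epsilon = epsilon,
                     max_outer = max_outer, tol = tol, max_inner = max_inner)
  structure(list(embedding = embedding, fit = fit),
            class = "mimlwel_model")
}

#' @export
print.mimlwel_model <- function(x, ...) {
  print(x$embedding); print(x$fit)
  invisible(x)
}

#' @rdname mimlwel_train
#' @param object A `mimlwel_model`.
#' @param bags List of bags to score.
#' @param ... Unused.
#' @export
predict.mimlwel_model <- function(object, bags, ...) {
  Phi <- embed_bags(object$embedding, bags)
  predict(object$fit, Phi)
}
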