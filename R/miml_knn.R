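# MIML-kNN baseline: neighbor/citer voting over Hausdorff bag distances.
# For a query bag, the voters are its n_neighbors nearest training bags
# (references) together with the training bags that would count the query
# among their own n_citers nearest bags (citers); the score of a label is
# the fraction of voters positive for it.

#' Fit a MIML-kNN model
#'
#' @param bags List of training bags.
#' @param Y Binary label matrix for the training bags (typically observed
#'   weak labels).
#' @param n_neighbors Number of nearest reference bags (default 10).
#' @param n_citers Number of citers each training bag considers (default 20);
#'   0 disables citation and reduces the method to plain kNN voting.
#' @param distance Bag distance: "avg" (default) or "max" Hausdorff.
#' @return An object of class `miml_knn`.
#' @export
miml_knn <- function(bags, Y, n_neighbors = 10L, n_citers = 20L,
                     distance = c("avg", "max")) {
  distance <- match.arg(distance)
  assert_binary_matrix(Y, "Y")
  if (!length(bags)) stopf("training set is empty")
  if (length(bags) != nrow(Y)) stopf("bags and Y disagree on the number of bags")
  if (n_neighbors < 1L) stopf("n_neighbors must be >= 1")
  if (n_neighbors > length(bags)) {
    stopf("n_neighbors (%d) exceeds the number of training bags (%d)",
          n_neighbors, length(bags))
  }
  if (n_citers < 0L) stopf("n_citers must be >= 0")
  structure(list(bags = bags, Y = Y, n_neighbors = as.integer(n_neighbors),
                 n_citers = as.integer(n_citers), distance = distance,
                 D_train = bag_dist_matrix(bags, distance)),
            class = "miml_knn")
}

#' @export
print.miml_knn <- function(x, ...) {
  cat(sprintf("<miml_knn> %d training bags, %d labels; %d neighbors, %d citers, %s Hausdorff\n",
              length(x$bags), ncol(x$Y), x$n_neighbors, x$n_citers, x$distance))
  invisible(x)
}

#' Predict labels with a MIML-kNN model
#'
#' References of a query are its `n_neighbors` nearest training bags; citers
#' are the training bags for which the query ranks among their `n_citers`
#' nearest bags within training-set-plus-query (distance ties are broken
#' toward the lower training index, so the query loses ties). The score of
#' label `l` is the fraction of the reference/citer union positive for `l`;
#' the binary call threshold is 0.5.
#'
#' @param object A [miml_knn()] model.
#' @param bags List of query bags.
#' @param ... Unused.
#' @return List with `scores` (n x L, in `[0, 1]`) and `binary`
#'   (`scores >= 0.5`).
#' @export
predict.miml_knn <- function(object, bags, ...) {
  if (inherits(bags, "miml_bag")) bags <- list(bags)
  m <- length(object$bags)
  Dq <- bag_cross_dist(bags, object$bags, object$distance)  # n_query x m
  L <- ncol(object$Y)
  scores <- matrix(0, length(bags), L)
  for (q in seq_along(bags)) {
    d <- Dq[q, ]
    refs <- order(d)[seq_len(object$n_neighbors)]  # order() ties -> lower index
    citers <- integer(0)
    if (object$n_citers > 0L) {
      # training bag t cites the query iff fewer than n_citers training bags
      # (other than t) are at distance <= d(t, query); ties favor training bags
      for (t in seq_len(m)) {
        closer <- sum(object$D_train[t, -t] <= d[t])
        if (closer < object$n_citers) citers <- c(citers, t)
      }
    }
    voters <- union(refs, citers)
    scores[q, ] <- colSums(object$Y[voters, , drop = FALSE]) / length(voters)
  }
  colnames(scores) <- colnames(object$Y)
  list(scores = scores, binary = (scores >= 0.5) * 1)
}
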