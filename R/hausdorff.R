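# Bag-to-bag distances (average and maximal Hausdorff) and PAM-style
# k-medoids clustering over a precomputed bag distance matrix. These are the
# geometric primitives behind both the bag embedding and the MIML-kNN
# baseline.

as_instance_matrix <- function(x) {
  if (inherits(x, "miml_bag")) x$instances else as.matrix(x)
}

# Squared Euclidean cross-distances between rows of A and rows of B,
# clamped at 0 against floating-point cancellation.
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Average Hausdorff distance between two bags
#'
#' `(sum_a min_b ||a-b|| + sum_b min_a ||a-b||) / (|A| + |B|)`: every
#' instance of each bag is matched to its nearest instance in the other bag
#' and the matched distances are averaged. Symmetric; zero iff each
#' instance of either bag coincides with some instance of the other.
#'
#' @param A,B Bags (`miml_bag`) or numeric matrices with instances as rows
#'   and a common number of columns.
#' @return Nonnegative scalar.
#' @export
avg_hausdorff <- function(A, B) {
  A <- as_instance_matrix(A); B <- as_instance_matrix(B)
  if (ncol(A) != ncol(B)) {
    stopf("instance dimension mismatch: %d vs %d", ncol(A), ncol(B))
  }
  D <- cross_dist(A, B)
  (sum(apply(D, 1, min)) + sum(apply(D, 2, min))) / (nrow(A) + nrow(B))
}

#' Maximal Hausdorff distance between two bags
#'
#' `max(max_a min_b ||a-b||, max_b min_a ||a-b||)`, the classical Hausdorff
#' metric between instance sets.
#'
#' @inheritParams avg_hausdorff
#' @return Nonnegative scalar.
#' @export
max_hausdorff <- function(A, B) {
  A <- as_instance_matrix(A); B <- as_instance_matrix(B)
  if (ncol(A) != ncol(B)) {
    stopf("instance dimension mismatch: %d vs %d", ncol(A), ncol(B))
  }
  D <- cross_dist(A, B)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# All pairwise bag distances between two bag lists, vectorized: stack all
# instances, compute one instance-level distance matrix, reduce each
# instance's distances to per-bag minima, then aggregate per bag pair.
bag_cross_dist <- function(bags_a, bags_b, method = c("avg", "max")) {
  method <- match.arg(method)
  Xa <- do.call(rbind, lapply(bags_a, as_instance_matrix))
  Xb <- do.call(rbind, lapply(bags_b, as_instance_matrix))
  na <- vapply(bags_a, function(b) nrow(as_instance_matrix(b)), integer(1))
  nb <- vapply(bags_b, function(b) nrow(as_instance_matrix(b)), integer(1))
  ga <- rep(seq_along(bags_a), na)
  gb <- rep(seq_along(bags_b), nb)
  D <- cross_dist(Xa, Xb)
  # Ma[i, j]: min distance from instance i of side a to bag j of side b
  Ma <- matrix(0, nrow(Xa), length(bags_b))
  for (j in seq_along(bags_b)) {
    cols <- which(gb == j)
    Ma[, j] <- if (length(cols) == 1L) D[, cols] else do.call(pmin, asplit(D[, cols, drop = FALSE], 2))
  }
  Mb <- matrix(0, nrow(Xb), length(bags_a))
  for (i in seq_along(bags_a)) {
    rows <- which(ga == i)
    Mb[, i] <- if (length(rows) == 1L) D[rows, ] else do.call(pmin, asplit(D[rows, , drop = FALSE], 1))
  }
  out <- if (method == "avg") {
    Sa <- rowsum(Ma, ga)                      # bags_a x bags_b sums of row minima
    Sb <- t(rowsum(Mb, gb))                   # bags_a x bags_b sums of col minima
    (Sa + Sb) / outer(na, nb, `+`)
  } else {
    Sa <- apply_group_max(Ma, ga)
    Sb <- t(apply_group_max(Mb, gb))
    pmax(Sa, Sb)
  }
  dimnames(out) <- NULL
  out
}

apply_group_max <- function(M, g) {
  out <- matrix(0, max(g), ncol(M))
  for (k in seq_len(max(g))) {
    rows <- which(g == k)
    out[k, ] <- if (length(rows) == 1L) M[rows, ] else do.call(pmax, asplit(M[rows, , drop = FALSE], 1))
  }
  out
}

#' Pairwise bag distance matrix
#'
#' @param bags List of bags.
#' @param method "avg" (average Hausdorff) or "max" (maximal Hausdorff).
#' @return Symmetric m x m numeric matrix with zero diagonal.
#' @export
bag_dist_matrix <- function(bags, method = c("avg", "max")) {
  method <- match.arg(method)
  D <- bag_cross_dist(bags, bags, method)
  D <- (D + t(D)) / 2   # symmetrize away floating-point asymmetry
  diag(D) <- 0
  D
}

#' k-medoids clustering on a bag distance matrix
#'
#' PAM-style: K medoids are drawn uniformly at random (seeded), then sweeps
#' of greedy swaps are applied — each sweep evaluates every
#' (medoid, non-medoid) exchange and applies the best strictly improving one
#' — until no swap improves the cost or `max_sweeps` is reached. The cost is
#' the sum over bags of the distance to the nearest medoid. Ties are broken
#' by the lowest index, so the result is deterministic given the seed.
#'
#' @param D m x m distance matrix (e.g. [bag_dist_matrix()]).
#' @param K Number of medoids, `1 <= K <= m`.
#' @param seed Integer seed for the initialization.
#' @param max_sweeps Maximum number of swap sweeps (default 100).
#' @return Sorted integer vector of K medoid indices.
#' @export
k_medoids <- function(D, K, seed, max_sweeps = 100L) {
  D <- as.matrix(D)
  m <- nrow(D)
  if (K > m) stopf("K (%d) cannot exceed the number of bags (%d)", K, m)
  if (K < 1L) stopf("K must be >= 1")
  if (K == m) return(seq_len(m))
  medoids <- sort(with_seed(seed, sample.int(m, K)))
  cost <- function(med) {
    sub <- D[, med, drop = FALSE]
    if (length(med) == 1L) sum(sub) else sum(do.call(pmin, asplit(sub, 2)))
  }
  cur <- cost(medoids)
  for (sweep in seq_len(max_sweeps)) {
    best <- list(gain = 0, med = NA_integer_, cand = NA_integer_)
    outside <- setdiff(seq_len(m), medoids)
    for (mi in medoids) {
      for (ci in outside) {
        trial <- c(setdiff(medoids, mi), ci)
        g <- cur - cost(trial)
        # strict improvement; ties resolved toward the earlier (mi, ci) pair
        if (g > best$gain + 1e-12) best <- list(gain = g, med = mi, cand = ci)
      }
    }
    if (best$gain <= 1e-12) break
    medoids <- sort(c(setdiff(medoids, best$med), best$cand))
    cur <- cur - best$gain
  }
  medoids
}
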