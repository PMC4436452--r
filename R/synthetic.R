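# Synthetic MIML data generator. Emulates the statistical structure of
# curated bacterial proteome MIML datasets: a few hundred bags,
# ~3.2 instances (domains) per bag, ~3.3 labels (GO terms) per bag with a
# heavily skewed (Zipf-like) label popularity so many labels are rare, and
# 216-dimensional instances living on the probability simplex like
# conjoint-triad frequency vectors. Each label has a prototype instance
# vector; a bag positive for a label contains at least one noisy copy of
# that label's prototype, and correlated label pairs share a prototype
# (highly relevant labels share common instances).

#' Specification of a synthetic MIML dataset
#'
#' @param m Number of bags (default 375).
#' @param L Number of candidate labels (default 60); labels that end up with
#'   no positive bag are dropped from the full matrix, so the realized label
#'   count can be smaller.
#' @param dim Instance dimension (default 216).
#' @param bag_size_mean,bag_size_sd Mean and sd of the per-bag instance
#'   count, `round(Normal)` truncated to `>= 1` (defaults 3.2 and 1.2).
#' @param labels_per_bag_mean Target mean number of labels per bag
#'   (default 3.3).
#' @param prototype_noise Sd of the Gaussian noise added to a prototype
#'   before projection back onto the simplex (default 0.015; same-family
#'   domains have nearly identical triad profiles).
#' @param background_rate Probability that a filler instance (a slot not
#'   needed to realize a label) is unstructured background noise rather than
#'   another noisy prototype copy (default 0.5).
#' @param correlated_pairs 2-column integer matrix of label index pairs that
#'   share a prototype; default: 3 adjacent-rank pairs just past the
#'   flattened head of the popularity law (none when `L` is too small).
#' @param zipf_exponent Exponent of the label popularity law (default 1.0).
#' @param pair_prob Probability that the partner of a sampled correlated
#'   label is added to the bag's label set (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 375L, L = 60L, dim = 216L,
                           bag_size_mean = 3.2, bag_size_sd = 1.2,
                           labels_per_bag_mean = 3.3,
                           prototype_noise = 0.015, background_rate = 0.5,
                           correlated_pairs = NULL, zipf_exponent = 1.0,
                           pair_prob = 0.5, seed = 1L) {
  if (m < 1L || L < 1L || dim < 1L) stopf("m, L and dim must be >= 1")
  if (labels_per_bag_mean > L) stopf("labels_per_bag_mean cannot exceed L")
  if (prototype_noise <= 0) stopf("prototype_noise must be positive")
  if (background_rate < 0 || background_rate > 1) stopf("background_rate must lie in [0, 1]")
  if (is.null(correlated_pairs)) {
    # three pairs just past the flattened head of the popularity law:
    # frequent enough to co-occur, without stacking onto the top labels
    l0 <- max(1L, ceiling(0.3 * L))
    correlated_pairs <- if (L >= l0 + 6L) cbind(l0 + c(1L, 3L, 5L), l0 + c(2L, 4L, 6L))
                        else matrix(integer(0), 0, 2)
  }
  correlated_pairs <- matrix(as.integer(correlated_pairs), ncol = 2)
  if (nrow(correlated_pairs) && (anyDuplicated(as.vector(correlated_pairs)) ||
                                 max(correlated_pairs) > L)) {
    stopf("correlated_pairs must be disjoint label index pairs within 1..L")
  }
  structure(list(m = as.integer(m), L = as.integer(L), dim = as.integer(dim),
                 bag_size_mean = bag_size_mean, bag_size_sd = bag_size_sd,
                 labels_per_bag_mean = labels_per_bag_mean,
                 prototype_noise = prototype_noise,
                 background_rate = background_rate,
                 correlated_pairs = correlated_pairs,
                 zipf_exponent = zipf_exponent, pair_prob = pair_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Label popularity: Zipf-like decay over popularity ranks, with the head
# flattened across the top ~15% of labels. A pure Zipf law at small L puts
# one label in well over half the bags, which real proteome annotations do
# not show (no GO molecular-function term annotates a majority of
# proteins); flattening the head keeps every label frequency realistic
# while preserving the long tail of rare labels.
label_popularity <- function(L, exponent) {
  l0 <- max(1L, ceiling(0.3 * L))
  w <- 1 / pmax(seq_len(L), l0)^exponent
  w / sum(w)
}

# Expected value of min(n, 1 + Poisson(lambda)) under the truncated rounded
# normal bag-size law; used to calibrate lambda so the realized labels/bag
# mean hits the requested target despite the cap at the bag size.
expected_capped_labels <- function(lambda, spec, nmax = 30L) {
  ks <- seq_len(nmax)
  pk <- stats::pnorm(ks + 0.5, spec$bag_size_mean, spec$bag_size_sd) -
    stats::pnorm(ks - 0.5, spec$bag_size_mean, spec$bag_size_sd)
  pk[1] <- stats::pnorm(1.5, spec$bag_size_mean, spec$bag_size_sd)  # mass below 1.5 -> 1
  pk <- pk / sum(pk)
  cmax <- ceiling(lambda + 10 * sqrt(lambda) + 20)
  cs <- 1 + 0:cmax
  pc <- stats::dpois(0:cmax, lambda)
  pc <- pc / sum(pc)
  sum(outer(pk, pc) * outer(ks, cs, pmin))
}

solve_label_lambda <- function(spec) {
  w <- label_popularity(spec$L, spec$zipf_exponent)
  target <- spec$labels_per_bag_mean
  # expected partner additions per bag: a sampled pair member whose partner
  # was not itself sampled adds the partner with pair_prob; marginal
  # inclusion of label l after p weighted draws is ~ 1 - (1 - w_l)^p
  additions_at <- function(p_mean) {
    if (!nrow(spec$correlated_pairs)) return(0)
    pi_l <- 1 - (1 - w)^p_mean
    a <- spec$correlated_pairs[, 1]; b <- spec$correlated_pairs[, 2]
    spec$pair_prob * sum(pi_l[a] * (1 - pi_l[b]) + pi_l[b] * (1 - pi_l[a]))
  }
  f <- function(lambda) {
    base <- expected_capped_labels(lambda, spec)
    base + additions_at(base) - target
  }
  upper_reachable <- f(50)
  if (upper_reachable < 0) {
    # target above what the bag-size cap allows; saturate
    return(50)
  }
  stats::uniroot(f, c(1e-3, 50))$root
}

#' Generate a synthetic MIML dataset with ground truth
#'
#' See [synthetic_spec()] for the generative model. All randomness derives
#' from the spec's seed; the same spec yields a bit-identical dataset.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a `miml_dataset` with full labels) and
#'   `truth` (list: `prototypes`, a label x dim matrix; `assignments`, per
#'   bag a list mapping instance row to the label ids it realizes, empty for
#'   background instances; `spec`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lambda <- solve_label_lambda(spec)
  terms <- sprintf("GO:%07d", seq_len(spec$L))
  w <- label_popularity(spec$L, spec$zipf_exponent)
  partner <- integer(spec$L)
  if (nrow(spec$correlated_pairs)) {
    partner[spec$correlated_pairs[, 1]] <- spec$correlated_pairs[, 2]
    partner[spec$correlated_pairs[, 2]] <- spec$correlated_pairs[, 1]
  }
  with_seed(spec$seed, {
    # sparse simplex prototypes; correlated pairs share one prototype
    prototypes <- t(vapply(seq_len(spec$L), function(l) {
      v <- stats::rgamma(spec$dim, shape = 0.05)
      if (sum(v) == 0) v[sample.int(spec$dim, 1)] <- 1
      v / sum(v)
    }, numeric(spec$dim)))
    for (p in seq_len(nrow(spec$correlated_pairs))) {
      prototypes[spec$correlated_pairs[p, 2], ] <- prototypes[spec$correlated_pairs[p, 1], ]
    }
    rownames(prototypes) <- terms

    bags <- vector("list", spec$m)
    assignments <- vector("list", spec$m)
    Y <- matrix(0, spec$m, spec$L, dimnames = list(NULL, terms))
    noisy_proto <- function(l) {
      proj_simplex(prototypes[l, ] + stats::rnorm(spec$dim, 0, spec$prototype_noise))
    }
    background <- function() {
      v <- stats::rgamma(spec$dim, shape = 0.05)
      if (sum(v) == 0) v[sample.int(spec$dim, 1)] <- 1
      v / sum(v)
    }
    for (i in seq_len(spec$m)) {
      n_i <- max(1L, as.integer(round(stats::rnorm(1, spec$bag_size_mean, spec$bag_size_sd))))
      c_raw <- 1L + stats::rpois(1, lambda)
      p_i <- min(n_i, c_raw, spec$L)
      proto_labels <- sample.int(spec$L, p_i, prob = w)
      inst <- matrix(0, n_i, spec$dim)
      ass <- vector("list", n_i)
      labels_i <- integer(0)
      for (j in seq_len(p_i)) {
        l <- proto_labels[j]
        inst[j, ] <- noisy_proto(l)
        realized <- l
        # a correlated partner drawn in rides on the shared prototype instance
        pl <- partner[l]
        if (pl > 0L && !(pl %in% proto_labels) && !(pl %in% labels_i) &&
            stats::runif(1) < spec$pair_prob) {
          realized <- c(realized, pl)
        }
        ass[[j]] <- terms[realized]
        labels_i <- union(labels_i, realized)
      }
      if (n_i > p_i) {
        for (j in seq.int(p_i + 1L, n_i)) {
          if (stats::runif(1) < spec$background_rate || p_i == 0L) {
            inst[j, ] <- background()
            ass[[j]] <- character(0)
          } else {
            l <- proto_labels[sample.int(p_i, 1)]
            inst[j, ] <- noisy_proto(l)
            ass[[j]] <- terms[l]
          }
        }
      }
      bags[[i]] <- new_bag(sprintf("bag_%04d", i), inst)
      assignments[[i]] <- ass
      Y[i, labels_i] <- 1
    }
  })
  keep <- colSums(Y) > 0
  dataset <- new_dataset(bags, Y[, keep, drop = FALSE], "full")
  truth <- list(prototypes = prototypes[keep, , drop = FALSE],
                assignments = assignments, spec = spec)
  list(dataset = dataset, truth = truth)
}

#' Summary statistics of a MIML dataset
#'
#' The four headline characteristics used to describe MIML proteome
#' datasets: number of examples (bags), number of label classes, instances
#' per bag and labels per example, the latter two as mean +/- sd (sample
#' standard deviation, n - 1 denominator).
#'
#' @param dataset A `miml_dataset`.
#' @return List with `m`, `L`, `instances_per_bag` (`c(mean, sd)`) and
#'   `labels_per_example` (`c(mean, sd)`).
#' @export
dataset_stats <- function(dataset) {
  stopifnot(inherits(dataset, "miml_dataset"))
  if (!length(dataset$bags)) stopf("dataset is empty")
  sizes <- vapply(dataset$bags, n_instances, integer(1))
  lab <- rowSums(dataset$Y)
  list(m = length(dataset$bags), L = ncol(dataset$Y),
       instances_per_bag = c(mean = mean(sizes), sd = stats::sd(sizes)),
       labels_per_example = c(mean = mean(lab), sd = stats::sd(lab)))
}

#' Closed-form expected micro-F1 of a label-frequency random predictor
#'
#' Benchmark for signal detection: a predictor that flags each label
#' independently with probability equal to that label's empirical frequency.
#' With `m_l` positives out of `m` bags and `p_l = m_l / m`, the expected
#' pooled counts are `E[TP] = sum_l p_l m_l`, `E[FP] = sum_l p_l (m - m_l)`
#' and `E[FN] = sum_l (1 - p_l) m_l`; the expected micro-F1 is taken as the
#' ratio of expectations `2 E[TP] / (2 E[TP] + E[FP] + E[FN])`.
#'
#' @param Y Full binary label matrix.
#' @return Scalar expected micro-F1.
#' @export
random_predictor_micro_f1 <- function(Y) {
  assert_binary_matrix(Y, "Y")
  m <- nrow(Y)
  ml <- colSums(Y)
  pl <- ml / m
  tp <- sum(pl * ml)
  fp <- sum(pl * (m - ml))
  fn <- sum((1 - pl) * ml)
  2 * tp / (2 * tp + fp + fn)
}
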