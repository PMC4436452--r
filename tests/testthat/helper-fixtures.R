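# Shared fixture builders. All fixtures are generated in code; file-based
# ones are written to tempfiles.

rand_bag <- function(id, n, d, seed) {
  set.seed(seed)
  new_bag(id, matrix(runif(n * d), n, d))
}

rand_bags <- function(m, d = 3, seed = 1, max_n = 4) {
  set.seed(seed)
  lapply(seq_len(m), function(i) {
    new_bag(sprintf("b%02d", i), matrix(runif(sample(max_n, 1) * d), ncol = d))
  })
}

rand_binary <- function(nr, nc, seed, p = 0.4) {
  set.seed(seed)
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small molecular-function ontology: root <- a <- b <- c plus a sibling
toy_obo <- function() {
  write_tmp(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0003674",
    "name: molecular_function",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000001",
    "namespace: molecular_function",
    "is_a: GO:0003674 ! molecular_function",
    "",
    "[Term]",
    "id: GO:0000002",
    "namespace: molecular_function",
    "is_a: GO:0000001",
    "",
    "[Term]",
    "id: GO:0000003",
    "namespace: molecular_function",
    "is_a: GO:0000002",
    "",
    "[Term]",
    "id: GO:0000009",
    "namespace: molecular_function",
    "is_a: GO:0003674",
    "",
    "[Term]",
    "id: GO:0000008",
    "namespace: biological_process",
    "is_a: GO:0000008",
    "",
    "[Term]",
    "id: GO:0000007",
    "namespace: molecular_function",
    "is_a: GO:0003674",
    "is_obsolete: true"
  ), ".obo")
}

# tiny dataset: bags with 1-D instances and a 2-label matrix
toy_dataset <- function(m = 6, seed = 3) {
  set.seed(seed)
  bags <- lapply(seq_len(m), function(i) {
    new_bag(sprintf("p%d", i), matrix(rnorm(2), 2, 1))
  })
  Y <- cbind(rep(c(1, 0), length.out = m), rep(1, m))
  colnames(Y) <- c("GO:0000001", "GO:0000002")
  mimlwel:::new_dataset(bags, Y, "full")
}

# brute-force bag distance oracles (independent of the implementation)
oracle_avg_hausdorff <- function(A, B) {
  da <- apply(A, 1, function(a) min(apply(B, 1, function(b) sqrt(sum((a - b)^2)))))
  db <- apply(B, 1, function(b) min(apply(A, 1, function(a) sqrt(sum((a - b)^2)))))
  (sum(da) + sum(db)) / (nrow(A) + nrow(B))
}

oracle_max_hausdorff <- function(A, B) {
  da <- apply(A, 1, function(a) min(apply(B, 1, function(b) sqrt(sum((a - b)^2)))))
  db <- apply(B, 1, function(b) min(apply(A, 1, function(a) sqrt(sum((a - b)^2)))))
  max(max(da), max(db))
}

oracle_kmedoids_cost <- function(D, medoids) {
  sum(apply(D[, medoids, drop = FALSE], 1, min))
}

oracle_best_kmedoids <- function(D, K) {
  combos <- utils::combn(nrow(D), K)
  costs <- apply(combos, 2, function(med) oracle_kmedoids_cost(D, med))
  min(costs)
}

# cell-by-cell multilabel metric oracles
oracle_metrics <- function(pred, truth) {
  nr <- nrow(pred); nc <- ncol(pred)
  mism <- 0; tp_g <- 0; fp_g <- 0; fn_g <- 0
  f1s <- numeric(nc)
  for (l in seq_len(nc)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_len(nr)) {
      p <- pred[i, l]; t <- truth[i, l]
      if (p != t) mism <- mism + 1
      if (p == 1 && t == 1) tp <- tp + 1
      if (p == 1 && t == 0) fp <- fp + 1
      if (p == 0 && t == 1) fn <- fn + 1
    }
    f1s[l] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    tp_g <- tp_g + tp; fp_g <- fp_g + fp; fn_g <- fn_g + fn
  }
  list(hl = mism / (nr * nc),
       maf1 = mean(f1s),
       mif1 = if (2 * tp_g + fp_g + fn_g == 0) 0 else 2 * tp_g / (2 * tp_g + fp_g + fn_g))
}
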