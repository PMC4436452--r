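# Evaluation protocol: repeated k-fold cross-validation under weak-label
# masking, weak-label-ratio sweeps with shared fold structure (so ratios are
# paired), and the mu/alpha parameter grid. Training labels are masked to
# the requested W.L.R. per training fold; held-out bags are scored against
# their FULL labels — recovering the masked positives is the point of
# weak-label learning.

method_registry <- function() {
  list(
    mimlwel = list(
      fit = function(bags, Y_hat, seed, args) {
        do.call(mimlwel_train, c(list(bags = bags, Y_hat = Y_hat, seed = seed), args))
      },
      predict = function(model, bags) predict(model, bags)
    ),
    mimlknn = list(
      fit = function(bags, Y_hat, seed, args) {
        args$n_neighbors <- min(args$n_neighbors %||% 10L, length(bags))
        do.call(miml_knn, c(list(bags = bags, Y = Y_hat), args))
      },
      predict = function(model, bags) predict(model, bags)
    )
  )
}

make_folds <- function(m, folds, seed) {
  perm <- with_seed(seed, sample.int(m))
  assign <- integer(m)
  assign[perm] <- rep(seq_len(folds), length.out = m)
  assign
}

#' Repeated cross-validation of a MIML method under weak-label masking
#'
#' Per repetition the bags are shuffled (seed-derived) into `folds`
#' near-equal folds. Per fold, the training labels are masked to the target
#' W.L.R., the method is fitted on the training bags and scored on the
#' held-out bags against their full labels. Fold assignment seeds depend
#' only on `(seed, rep)` — never on the ratio or the method — so sweeps over
#' ratios or methods with the same seed are paired fold for fold.
#'
#' @param dataset A `miml_dataset` with full labels.
#' @param method "mimlwel" or "mimlknn".
#' @param folds Folds per repetition (default 10).
#' @param reps Repetitions (default 10).
#' @param wlr Weak-label ratio for the training folds, in (0, 1]; 1 means no
#'   masking (default 0.8).
#' @param seed Integer seed; the full procedure is reproducible from it.
#' @param method_args Named list of extra arguments for the method.
#' @return An object of class `cv_result`: `cells` (data.frame with one row
#'   per rep x fold and the three metrics), `summary` (mean and sd per
#'   metric), `fold_assignments` (reps x m matrix) and `config`.
#' @export
run_repeated_cv <- function(dataset, method = c("mimlwel", "mimlknn"),
                            folds = 10L, reps = 10L, wlr = 0.8, seed = 1L,
                            method_args = list()) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "miml_dataset"))
  if (dataset$role != "full") stopf("cross-validation requires full labels for scoring")
  m <- length(dataset$bags)
  if (folds > m) stopf("folds (%d) exceeds the number of bags (%d)", folds, m)
  if (folds < 2L) stopf("need at least 2 folds")
  if (wlr <= 0 || wlr > 1) stopf("wlr must lie in (0, 1]")
  reg <- method_registry()[[method]]
  cells <- list()
  fold_assignments <- matrix(0L, reps, m)
  for (r in seq_len(reps)) {
    assign <- make_folds(m, folds, derive_seed(seed, "folds", r))
    fold_assignments[r, ] <- assign
    for (f in seq_len(folds)) {
      test_idx <- which(assign == f)
      train_idx <- which(assign != f)
      Y_train <- dataset$Y[train_idx, , drop = FALSE]
      Y_hat <- if (wlr < 1) {
        mask_labels(Y_train, wlr, derive_seed(seed, "mask", r, f))
      } else {
        Y_train
      }
      model <- reg$fit(dataset$bags[train_idx], Y_hat,
                       derive_seed(seed, "fit", r, f), method_args)
      pred <- reg$predict(model, dataset$bags[test_idx])
      met <- multilabel_metrics(pred$binary, dataset$Y[test_idx, , drop = FALSE])
      cells[[length(cells) + 1L]] <- data.frame(
        rep = r, fold = f,
        hamming_loss = met$hamming_loss,
        macro_f1 = met$macro_f1,
        micro_f1 = met$micro_f1)
    }
  }
  cells <- do.call(rbind, cells)
  summ <- lapply(c(hamming_loss = "hamming_loss", macro_f1 = "macro_f1",
                   micro_f1 = "micro_f1"),
                 function(col) c(mean = mean(cells[[col]]), sd = stats::sd(cells[[col]])))
  structure(list(cells = cells, summary = summ,
                 fold_assignments = fold_assignments,
                 config = list(method = method, folds = folds, reps = reps,
                               wlr = wlr, seed = seed, method_args = method_args)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cv_result> %s, %dx%d-fold CV, W.L.R. %.2f\n",
              cfg$method, cfg$reps, cfg$folds, cfg$wlr))
  for (nm in names(x$summary)) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", nm, x$summary[[nm]]["mean"],
                x$summary[[nm]]["sd"]))
  }
  invisible(x)
}

#' Weak-label-ratio sweep
#'
#' Runs [run_repeated_cv()] at each ratio with the same seed, so fold
#' structure and masking draws are shared and results are paired across
#' ratios.
#'
#' @inheritParams run_repeated_cv
#' @param ratios Weak-label ratios in (0, 1] (default `c(0.2, 0.4, 0.6,
#'   0.8)`, the 20%-80% sweep at 20% intervals).
#' @return Named list of `cv_result`, one per ratio.
#' @export
wlr_sweep <- function(dataset, method = "mimlwel",
                      ratios = c(0.2, 0.4, 0.6, 0.8),
                      folds = 10L, reps = 10L, seed = 1L,
                      method_args = list()) {
  if (!length(ratios)) stopf("ratio list must not be empty")
  if (any(ratios <= 0 | ratios > 1)) stopf("ratios must lie in (0, 1]")
  out <- lapply(ratios, function(r) {
    run_repeated_cv(dataset, method, folds = folds, reps = reps, wlr = r,
                    seed = seed, method_args = method_args)
  })
  names(out) <- sprintf("wlr_%g", ratios)
  out
}

#' mu/alpha parameter grid for MIMLwel
#'
#' Evaluates MIMLwel at every (mu, alpha) combination by repeated CV at a
#' fixed W.L.R. and reports the best cell per metric (lowest Hamming loss,
#' highest macro/micro-F1).
#'
#' @inheritParams run_repeated_cv
#' @param mu_values Scaling factors (default `seq(0.2, 1.0, by = 0.2)`).
#' @param alpha_values Medoid fractions (default `seq(0.02, 0.1, by = 0.02)`).
#' @param wlr Weak-label ratio (default 0.8).
#' @return An object of class `param_grid_result`: `grid` (data.frame with
#'   mu, alpha and metric means/sds) and `best` (named list of argmax rows).
#' @export
param_grid <- function(dataset, mu_values = seq(0.2, 1.0, by = 0.2),
                       alpha_values = seq(0.02, 0.1, by = 0.02),
                       wlr = 0.8, folds = 10L, reps = 10L, seed = 1L,
                       method_args = list()) {
  if (any(mu_values <= 0) || any(alpha_values <= 0)) {
    stopf("mu and alpha values must be positive")
  }
  rows <- list()
  for (mu in mu_values) {
    for (alpha in alpha_values) {
      args <- utils::modifyList(method_args, list(mu = mu, alpha = alpha))
      cv <- run_repeated_cv(dataset, "mimlwel", folds = folds, reps = reps,
                            wlr = wlr, seed = seed, method_args = args)
      rows[[length(rows) + 1L]] <- data.frame(
        mu = mu, alpha = alpha,
        hamming_loss = cv$summary$hamming_loss["mean"],
        hamming_loss_sd = cv$summary$hamming_loss["sd"],
        macro_f1 = cv$summary$macro_f1["mean"],
        macro_f1_sd = cv$summary$macro_f1["sd"],
        micro_f1 = cv$summary$micro_f1["mean"],
        micro_f1_sd = cv$summary$micro_f1["sd"])
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  best <- list(
    hamming_loss = grid[which.min(grid$hamming_loss), c("mu", "alpha", "hamming_loss")],
    macro_f1 = grid[which.max(grid$macro_f1), c("mu", "alpha", "macro_f1")],
    micro_f1 = grid[which.max(grid$micro_f1), c("mu", "alpha", "micro_f1")])
  structure(list(grid = grid, best = best,
                 config = list(wlr = wlr, folds = folds, reps = reps, seed = seed)),
            class = "param_grid_result")
}

#' @export
print.param_grid_result <- function(x, ...) {
  cat(sprintf("<param_grid_result> %d cells (W.L.R. %.2f)\n", nrow(x$grid), x$config$wlr))
  cat("best per metric:\n")
  for (nm in names(x$best)) {
    b <- x$best[[nm]]
    cat(sprintf("  %-12s mu=%.2g alpha=%.2g (%.3f)\n", nm, b$mu, b$alpha, b[[3]]))
  }
  invisible(x)
}

#' Compare MIMLwel against MIML-kNN with paired significance tests
#'
#' Runs both methods through [run_repeated_cv()] on identical folds and
#' applies [paired_t_test()] per metric over the rep x fold cells. A
#' comparison is marked when MIMLwel is better on the metric and the paired
#' difference is significant at the given level (the filled-circle
#' convention of method-comparison tables).
#'
#' @inheritParams run_repeated_cv
#' @param level Significance level for the paired t-tests (default 0.95).
#' @param mimlwel_args,mimlknn_args Extra arguments per method.
#' @return An object of class `method_comparison` with both `cv_result`s and
#'   a per-metric comparison table.
#' @export
compare_methods <- function(dataset, folds = 10L, reps = 10L, wlr = 0.8,
                            seed = 1L, level = 0.95,
                            mimlwel_args = list(), mimlknn_args = list()) {
  cv_wel <- run_repeated_cv(dataset, "mimlwel", folds, reps, wlr, seed, mimlwel_args)
  cv_knn <- run_repeated_cv(dataset, "mimlknn", folds, reps, wlr, seed, mimlknn_args)
  stopifnot(identical(cv_wel$fold_assignments, cv_knn$fold_assignments))
  comp <- lapply(c(hamming_loss = "hamming_loss", macro_f1 = "macro_f1",
                   micro_f1 = "micro_f1"), function(col) {
    tt <- paired_t_test(cv_wel$cells[[col]], cv_knn$cells[[col]], level)
    better <- if (col == "hamming_loss") {
      mean(cv_wel$cells[[col]]) < mean(cv_knn$cells[[col]])
    } else {
      mean(cv_wel$cells[[col]]) > mean(cv_knn$cells[[col]])
    }
    list(mimlwel = mean(cv_wel$cells[[col]]), mimlknn = mean(cv_knn$cells[[col]]),
         t = tt$t, p = tt$p, mimlwel_better = better,
         marked = better && tt$significant)
  })
  structure(list(mimlwel = cv_wel, mimlknn = cv_knn, comparison = comp,
                 level = level),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> MIMLwel vs MIML-kNN\n")
  for (nm in names(x$comparison)) {
    c <- x$comparison[[nm]]
    cat(sprintf("  %-12s %.3f vs %.3f  p=%.3g%s\n", nm, c$mimlwel, c$mimlknn,
                c$p, if (c$marked) " *" else ""))
  }
  invisible(x)
}
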