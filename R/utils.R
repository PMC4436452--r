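# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a base seed and a stage label
#'
#' All stochastic stages draw their randomness from a single user-supplied
#' seed; per-stage seeds are derived deterministically from the stage name so
#' that a full pipeline run is reproducible end to end while stages remain
#' decoupled.
#'
#' @param seed Integer base seed.
#' @param ... Character or integer labels identifying the stage (e.g. stage
#'   name, repetition index, fold index).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(labels)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h %% 2147483646L + 1L)
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the caller's
# RNG state afterwards (functions taking a seed must not disturb the session).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Euclidean projection of a numeric vector onto the probability simplex
# (Duchi et al. sort-based algorithm). Used to keep synthetic instances on
# the same simplex as triad-frequency vectors.
proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_binary_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !all(x %in% c(0, 1))) {
    stopf("'%s' must be a binary (0/1) matrix", name)
  }
  invisible(x)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stopf("matrices must have identical dimensions (got %s vs %s)",
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  }
  invisible(NULL)
}
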