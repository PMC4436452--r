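# JSON persistence for trained MIMLwel models, so the train and predict
# pipeline stages can run as separate processes.

MODEL_SCHEMA_VERSION <- "1.0"

#' Write and read a trained MIMLwel model as JSON
#'
#' @param model A `mimlwel_model` from [mimlwel_train()].
#' @param path Output (input) file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   `mimlwel_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mimlwel_model"))
  emb <- model$embedding
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    embedding = list(
      medoids = lapply(emb$medoids, function(b) {
        list(bag_id = b$bag_id, instances = mat_rows(b$instances))
      }),
      delta = emb$delta, mu = emb$mu, alpha = emb$alpha, K = emb$K,
      distance = emb$distance),
    fit = list(
      W = mat_rows(model$fit$W),
      labels = colnames(model$fit$Y_hat),
      eta = model$fit$eta, epsilon = model$fit$epsilon,
      tau = model$fit$tau, trace = model$fit$trace,
      Y_bar = mat_rows(model$fit$Y_bar),
      Y_hat = mat_rows(model$fit$Y_hat))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    stopf("model schema version mismatch: found '%s', expected '%s'",
          doc$schema_version %||% "<missing>", MODEL_SCHEMA_VERSION)
  }
  num_matrix <- function(rows) {
    do.call(rbind, lapply(rows, function(r) vapply(r, as.numeric, numeric(1))))
  }
  medoids <- lapply(doc$embedding$medoids, function(b) {
    new_bag(as.character(b$bag_id), num_matrix(b$instances))
  })
  embedding <- structure(list(
    medoids = medoids, medoid_idx = NULL,
    delta = as.numeric(doc$embedding$delta), mu = as.numeric(doc$embedding$mu),
    alpha = as.numeric(doc$embedding$alpha), K = as.integer(doc$embedding$K),
    distance = as.character(doc$embedding$distance)), class = "bag_embedding")
  labels <- vapply(doc$fit$labels, as.character, character(1))
  Y_hat <- num_matrix(doc$fit$Y_hat); colnames(Y_hat) <- labels
  Y_bar <- num_matrix(doc$fit$Y_bar); colnames(Y_bar) <- labels
  fit <- structure(list(
    W = num_matrix(doc$fit$W), Y_bar = Y_bar, Y_hat = Y_hat,
    trace = vapply(doc$fit$trace, as.numeric, numeric(1)),
    eta = as.numeric(doc$fit$eta), epsilon = as.numeric(doc$fit$epsilon),
    tau = if (is.null(doc$fit$tau)) NULL else as.numeric(doc$fit$tau),
    relations = NULL, budget = NULL), class = "mimlwel_fit")
  structure(list(embedding = embedding, fit = fit), class = "mimlwel_model")
}
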