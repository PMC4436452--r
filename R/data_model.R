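# Core containers: bags of instances, label matrices, MIML datasets.
#
# A protein is modelled as a *bag*: an ordered set of instance vectors, one
# per conserved domain. Annotations live in an m x L binary label matrix in
# one of three roles: "full" (complete ground truth Y), "observed" (weak
# labels Y-hat: a subset of the true positives; 0 means unknown), and
# "corrected" (the learner's completed matrix Y-bar >= Y-hat).

#' Construct a bag of instances
#'
#' @param bag_id Character scalar identifying the protein.
#' @param instances Numeric matrix with one row per instance (domain) and a
#'   fixed number of columns (default 216 for conjoint-triad features).
#' @return An object of class `miml_bag`.
#' @export
new_bag <- function(bag_id, instances) {
  if (!is.character(bag_id) || length(bag_id) != 1L || !nzchar(bag_id)) {
    stopf("bag_id must be a non-empty character scalar")
  }
  instances <- as.matrix(instances)
  if (nrow(instances) < 1L) stopf("bag '%s' must contain at least one instance", bag_id)
  if (!is.numeric(instances) || anyNA(instances)) {
    stopf("bag '%s' has non-numeric or missing instance values", bag_id)
  }
  structure(list(bag_id = bag_id, instances = unname(instances)),
            class = "miml_bag")
}

#' @export
print.miml_bag <- function(x, ...) {
  cat(sprintf("<miml_bag> %s: %d instance(s) x %d dims\n",
              x$bag_id, nrow(x$instances), ncol(x$instances)))
  invisible(x)
}

n_instances <- function(bag) nrow(bag$instances)

bag_dim <- function(bag) ncol(bag$instances)

#' Assemble a MIML dataset from bags and annotation sets
#'
#' Builds the bag x label binary matrix from per-protein GO term sets. The
#' label space defaults to the sorted union of observed terms; when building
#' a `full` matrix, columns without a single positive are dropped (a label no
#' protein carries is unlearnable and would make macro-F1 degenerate). The GO
#' molecular-function root (`GO:0003674`) is never emitted as a label: it is
#' positive for every annotated protein and carries no information.
#'
#' @param bags List of [new_bag()] objects with unique ids.
#' @param annotations Named list mapping bag_id to a character vector of GO
#'   term ids (possibly empty).
#' @param label_space Optional character vector fixing the label columns
#'   (sorted lexicographically). Required to retain all-zero columns, which
#'   is only permitted for `role = "observed"`.
#' @param role One of "full" or "observed".
#' @return An object of class `miml_dataset` with elements `bags`, `Y`
#'   (binary matrix with bag ids as rownames and GO ids as colnames) and
#'   `role`.
#' @export
build_dataset <- function(bags, annotations, label_space = NULL,
                          role = c("full", "observed")) {
  role <- match.arg(role)
  ids <- vapply(bags, function(b) b$bag_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate bag_id: %s", ids[duplicated(ids)][1])
  unknown <- setdiff(names(annotations), ids)
  if (length(unknown)) {
    stopf("annotation references unknown bag_id '%s'", unknown[1])
  }
  missing_ann <- setdiff(ids, names(annotations))
  if (length(missing_ann)) {
    stopf("bag '%s' has no annotation entry (use an empty set for unannotated bags)",
          missing_ann[1])
  }
  go_root <- "GO:0003674"
  terms <- lapply(annotations[ids], function(s) setdiff(unique(as.character(s)), go_root))
  if (is.null(label_space)) {
    label_space <- sort(unique(unlist(terms)))
  } else {
    label_space <- sort(unique(setdiff(as.character(label_space), go_root)))
  }
  if (!length(label_space)) stopf("no labels: all annotation sets are empty")
  Y <- matrix(0, nrow = length(bags), ncol = length(label_space),
              dimnames = list(ids, label_space))
  for (i in seq_along(terms)) {
    hit <- intersect(terms[[i]], label_space)
    Y[i, hit] <- 1
  }
  if (role == "full") {
    keep <- colSums(Y) > 0
    if (!any(keep)) stopf("no labels: every column is empty")
    Y <- Y[, keep, drop = FALSE]
  }
  new_dataset(bags, Y, role)
}

new_dataset <- function(bags, Y, role) {
  ids <- vapply(bags, function(b) b$bag_id, character(1))
  stopifnot(length(bags) == nrow(Y))
  dims <- vapply(bags, bag_dim, integer(1))
  if (length(unique(dims)) != 1L) stopf("bags have inconsistent instance dimensions")
  rownames(Y) <- ids
  structure(list(bags = bags, Y = Y, role = role), class = "miml_dataset")
}

#' @export
print.miml_dataset <- function(x, ...) {
  cat(sprintf("<miml_dataset> %d bags x %d labels (role=%s), instance dim %d\n",
              length(x$bags), ncol(x$Y), x$role, bag_dim(x$bags[[1]])))
  invisible(x)
}

#' @rdname build_dataset
#' @param x A `miml_dataset`.
#' @export
label_space <- function(x) colnames(x$Y)

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of the header line;
#' sequences are uppercased with line breaks removed.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stopf("malformed FASTA file '%s': %s",
                                             path, conditionMessage(e)))
  if (!length(seqs)) stopf("FASTA file '%s' contains no records", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad)) stopf("FASTA record %d has an empty header", bad[1])
  widths <- Biostrings::width(seqs)
  if (any(widths == 0L)) {
    stopf("FASTA record '%s' has an empty sequence", ids[which(widths == 0L)[1]])
  }
  data.frame(id = ids, sequence = toupper(as.character(seqs)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a per-protein domain table
#'
#' The table is the tabular stand-in for conserved-domain detection output:
#' one row per domain with the protein it belongs to, its rank (order within
#' the protein, 1-based) and its amino-acid sequence.
#'
#' @param path Path to a TSV file with header columns `protein_id`, `rank`,
#'   `sequence`.
#' @return A data.frame with those columns, grouped per protein (first
#'   appearance order) and sorted by rank within protein.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stopf("domain table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "rank", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("domain table missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$rank <- suppressWarnings(as.integer(df$rank))
  if (anyNA(df$rank) || any(df$rank < 1L)) stopf("domain table 'rank' must be integers >= 1")
  if (any(!nzchar(df$sequence))) {
    stopf("empty domain sequence for protein '%s'", df$protein_id[!nzchar(df$sequence)][1])
  }
  key <- paste(df$protein_id, df$rank)
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stopf("duplicate (protein_id, rank) pair: ('%s', %d)", dup$protein_id[1], dup$rank[1])
  }
  df$sequence <- toupper(df$sequence)
  proteins <- unique(df$protein_id)
  df <- df[order(match(df$protein_id, proteins), df$rank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a per-protein GO annotation table
#'
#' @param path Path to a TSV file with header columns `protein_id` and
#'   `go_terms` (semicolon-separated GO ids; may be empty).
#' @return Named list mapping protein_id to a character vector of GO ids.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stopf("annotation table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "go_terms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("annotation table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$protein_id)) {
    stopf("duplicate protein_id in annotation table: '%s'",
          df$protein_id[duplicated(df$protein_id)][1])
  }
  ann <- lapply(df$go_terms, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  })
  names(ann) <- df$protein_id
  ann
}

# ---- JSON serialization -----------------------------------------------------

DATASET_SCHEMA_VERSION <- "1.0"

#' Write and read a MIML dataset as a JSON document
#'
#' Serialization is a single JSON document with an explicit `schema_version`
#' so that datasets survive package upgrades; `read_dataset(write_dataset(x))`
#' reproduces `x` exactly (numbers are written at full precision).
#'
#' @param dataset A `miml_dataset`.
#' @param path Output (input) file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the `miml_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "miml_dataset"))
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  doc <- list(
    schema_version = DATASET_SCHEMA_VERSION,
    label_space = as.list(colnames(dataset$Y)),
    labels = list(role = dataset$role, values = mat_rows(dataset$Y)),
    bags = lapply(dataset$bags, function(b) {
      list(bag_id = b$bag_id, instances = mat_rows(b$instances))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stopf("dataset file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema_version, DATASET_SCHEMA_VERSION)) {
    stopf("dataset schema version mismatch: found '%s', expected '%s'",
          doc$schema_version %||% "<missing>", DATASET_SCHEMA_VERSION)
  }
  labels <- vapply(doc$label_space, as.character, character(1))
  bags <- lapply(doc$bags, function(b) {
    inst <- b$instances
    if (!length(inst)) stopf("bag '%s' has no instances", b$bag_id %||% "<unnamed>")
    m <- do.call(rbind, lapply(inst, function(row) vapply(row, as.numeric, numeric(1))))
    new_bag(as.character(b$bag_id), m)
  })
  rows <- doc$labels$values
  Y <- do.call(rbind, lapply(rows, function(r) vapply(r, as.numeric, numeric(1))))
  colnames(Y) <- labels
  assert_binary_matrix(Y, "labels")
  role <- as.character(doc$labels$role)
  if (!role %in% c("full", "observed", "corrected")) {
    stopf("unknown label matrix role '%s'", role)
  }
  new_dataset(bags, Y, role)
}
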