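# Conjoint-triad featurization: each domain sequence becomes a frequency
# vector over 3-residue windows after mapping the 20 standard amino acids to
# 6 physicochemical classes, giving 6^3 = 216 triad types.

#' Construct a 6-class conjoint-triad alphabet
#'
#' The 20 standard amino acids are partitioned into 6 classes; a triad type
#' is the ordered triple of classes of 3 consecutive residues, so there are
#' exactly 6^3 = 216 triad types. The default partition is a Dayhoff-style
#' grouping: cysteine alone; small/polar (A, G, P, S, T); acidic and amide
#' (D, E, N, Q); basic (H, K, R); aliphatic hydrophobic (I, L, M, V);
#' aromatic (F, W, Y). Ambiguity codes (B, J, O, U, X, Z) map to no class;
#' windows containing them are skipped rather than the sequence rejected.
#'
#' @param groups List of 6 character vectors partitioning the 20 standard
#'   residues. Order defines class ids 0-5.
#' @return An object of class `triad_alphabet` with elements `groups` and
#'   `map` (named integer vector residue -> class id).
#' @export
triad_alphabet <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- list("C",
                   c("A", "G", "P", "S", "T"),
                   c("D", "E", "N", "Q"),
                   c("H", "K", "R"),
                   c("I", "L", "M", "V"),
                   c("F", "W", "Y"))
  }
  groups <- lapply(groups, function(g) toupper(as.character(g)))
  if (length(groups) != 6L) stopf("triad alphabet needs exactly 6 classes (got %d)", length(groups))
  all_res <- unlist(groups)
  if (anyDuplicated(all_res)) {
    stopf("residue '%s' appears in more than one class", all_res[duplicated(all_res)][1])
  }
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(all_res, standard)) {
    stopf("classes must partition the 20 standard residues exactly")
  }
  map <- integer(0)
  for (k in seq_along(groups)) map[groups[[k]]] <- k - 1L
  structure(list(groups = groups, map = map), class = "triad_alphabet")
}

#' Read a triad alphabet from a JSON config file
#'
#' @param path JSON file containing an object mapping each standard residue
#'   to a class id in 0-5.
#' @return A `triad_alphabet`.
#' @export
read_alphabet_config <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- sort(unique(unlist(m)))
  if (!identical(as.integer(ids), 0:5)) stopf("alphabet config must use class ids 0-5")
  groups <- lapply(0:5, function(k) names(m)[unlist(m) == k])
  triad_alphabet(groups)
}

#' Encode a sequence as a 216-dimensional triad frequency vector
#'
#' Slides a window of 3 consecutive residues along the sequence; a window is
#' valid iff all 3 residues map to a class. Counts per triad type (index
#' `36*c1 + 6*c2 + c3`) are divided by the number of valid windows, so the
#' output is a probability vector.
#'
#' @param sequence Amino-acid string.
#' @param alphabet A [triad_alphabet()].
#' @param id Optional identifier used in error messages.
#' @return Numeric vector of length 216, nonnegative, summing to 1.
#' @export
encode_triads <- function(sequence, alphabet = triad_alphabet(), id = NULL) {
  stopifnot(inherits(alphabet, "triad_alphabet"))
  label <- id %||% if (nchar(sequence) > 24) paste0(substr(sequence, 1, 24), "...") else sequence
  res <- strsplit(toupper(sequence), "")[[1]]
  cls <- unname(alphabet$map[res])  # NA for residues outside the 20 standard
  n <- length(cls)
  if (n < 3L) stopf("sequence '%s' has no valid triad window", label)
  c1 <- cls[1:(n - 2)]; c2 <- cls[2:(n - 1)]; c3 <- cls[3:n]
  idx <- 36L * c1 + 6L * c2 + c3 + 1L
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stopf("sequence '%s' has no valid triad window", label)
  tabulate(idx, nbins = 216L) / length(idx)
}

#' Featurize a protein's domains into a bag
#'
#' @param domains Data.frame with columns `protein_id`, `rank`, `sequence`
#'   for a single protein (as returned by [read_domain_table()]).
#' @param alphabet A [triad_alphabet()].
#' @return A `miml_bag` with one 216-dim instance per domain, in rank order.
#' @export
featurize_protein <- function(domains, alphabet = triad_alphabet()) {
  domains <- as.data.frame(domains)
  if (!nrow(domains)) stopf("protein has no domains")
  pid <- unique(domains$protein_id)
  if (length(pid) != 1L) stopf("featurize_protein expects a single protein (got %d)", length(pid))
  domains <- domains[order(domains$rank), , drop = FALSE]
  inst <- matrix(0, nrow(domains), 216L)
  for (i in seq_len(nrow(domains))) {
    inst[i, ] <- tryCatch(
      encode_triads(domains$sequence[i], alphabet),
      error = function(e) stopf("protein '%s', domain rank %d: %s",
                                pid, domains$rank[i], conditionMessage(e)))
  }
  new_bag(pid, inst)
}

#' Featurize every protein in a domain table
#'
#' @param domain_table Data.frame from [read_domain_table()].
#' @param alphabet A [triad_alphabet()].
#' @return List of `miml_bag`, one per protein, in first-appearance order.
#' @export
featurize_proteins <- function(domain_table, alphabet = triad_alphabet()) {
  split_idx <- split(seq_len(nrow(domain_table)), domain_table$protein_id)
  order_first <- unique(domain_table$protein_id)
  lapply(order_first, function(pid) {
    featurize_protein(domain_table[split_idx[[pid]], , drop = FALSE], alphabet)
  })
}
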