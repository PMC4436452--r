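# Gene Ontology molecular-function DAG: OBO parsing and true-path
# propagation. Only is_a edges are used; part_of and other relationship
# types are ignored (is_a is the conservative closure for the
# molecular-function hierarchy). The ontology root GO:0003674 anchors the
# graph but is never emitted as a label.

GO_MF_ROOT <- "GO:0003674"

#' Parse a molecular-function subset of an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas, keeps terms in the `molecular_function` namespace,
#' drops obsolete terms, records child-to-parent `is_a` edges and verifies
#' acyclicity and connectivity to the root.
#'
#' @param path Path to an OBO 1.2 file.
#' @return An object of class `go_dag`: list with `nodes` (character vector
#'   of GO ids, root included), `parents` (named list: child id -> character
#'   vector of parent ids) and `root`.
#' @export
parse_obo_subset <- function(path) {
  if (!file.exists(path)) stopf("OBO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # split into stanzas at [Term] markers; ignore the header and other stanzas
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  if (!length(term_starts)) stopf("no [Term] stanzas in '%s'", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    get_vals <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "", grep(paste0("^", key, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)  # strip trailing OBO comments
    }
    id <- get_vals("id")
    if (length(id) != 1L) next
    terms[[id]] <- list(
      namespace = get_vals("namespace"),
      obsolete = any(grepl("^is_obsolete:\\s*true", block)),
      is_a = vapply(strsplit(get_vals("is_a"), "\\s+"), `[`, character(1), 1L)
    )
  }
  keep <- names(terms)[vapply(terms, function(t) {
    identical(t$namespace, "molecular_function") && !t$obsolete
  }, logical(1))]
  if (!length(keep)) stopf("no molecular_function terms in '%s'", path)
  parents <- lapply(terms[keep], function(t) unique(t$is_a))
  # every is_a target must itself be a retained term
  for (child in keep) {
    bad <- setdiff(parents[[child]], keep)
    if (length(bad)) stopf("term '%s' has is_a to unknown id '%s'", child, bad[1])
  }
  dag <- structure(list(nodes = keep, parents = parents, root = GO_MF_ROOT),
                   class = "go_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stopf("ontology contains a cycle: %s", paste(cyc, collapse = " -> "))
  }
  if (!GO_MF_ROOT %in% dag$nodes) {
    stopf("root term %s absent from the molecular_function subset", GO_MF_ROOT)
  }
  orphan <- setdiff(dag$nodes[vapply(dag$parents, length, integer(1)) == 0L], GO_MF_ROOT)
  if (length(orphan)) {
    stopf("term '%s' has no is_a path to the root %s", orphan[1], GO_MF_ROOT)
  }
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d molecular_function terms, %d is_a edges, root %s\n",
              length(x$nodes), sum(lengths(x$parents)), x$root))
  invisible(x)
}

# Kahn's algorithm; if the edge set has a cycle, walk parent pointers among
# the unresolved nodes to extract one concrete cycle for the error message.
find_cycle <- function(dag) {
  indeg <- setNames(integer(length(dag$nodes)), dag$nodes)
  for (ps in dag$parents) for (p in ps) indeg[p] <- indeg[p] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in dag$parents[[n]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(dag$nodes)) return(NULL)
  stuck <- names(indeg)[indeg > 0L]
  path <- stuck[1]
  repeat {
    nxt <- intersect(dag$parents[[path[length(path)]]], stuck)[1]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
  }
}

#' Propagate GO annotations up the is_a hierarchy (true-path rule)
#'
#' A protein annotated with a term implicitly carries every ancestor of that
#' term. Returns the input terms together with all their is_a ancestors,
#' excluding the ontology root (which is positive for every annotated protein
#' and therefore uninformative as a label).
#'
#' @param direct_terms Character vector of GO ids present in `dag`.
#' @param dag A [parse_obo_subset()] result.
#' @return Sorted character vector of propagated GO ids.
#' @export
propagate_annotations <- function(direct_terms, dag) {
  stopifnot(inherits(dag, "go_dag"))
  direct_terms <- unique(as.character(direct_terms))
  unknown <- setdiff(direct_terms, dag$nodes)
  if (length(unknown)) stopf("unknown GO term '%s'", unknown[1])
  out <- character(0)
  frontier <- direct_terms
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), out)
  }
  sort(setdiff(out, dag$root))
}
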