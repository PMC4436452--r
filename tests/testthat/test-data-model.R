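test_that("FASTA reading takes the first header token and preserves order", {
  p <- write_tmp(c(">p1 some description", "MKV", ">p2", "AC", "DE"), ".fasta")
  fa <- read_fasta(p)
  expect_equal(fa$id, c("p1", "p2"))
  expect_equal(fa$sequence, c("MKV", "ACDE"))

  single <- read_fasta(write_tmp(c(">p1", "mkv"), ".fasta"))
  expect_equal(single$sequence, "MKV")
})

test_that("FASTA records with empty sequences are rejected by name", {
  p <- write_tmp(c(">p1", "", ">p2", "AA"), ".fasta")
  expect_error(read_fasta(p), "p1")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("domain tables are grouped by protein and sorted by rank", {
  p <- write_tmp(c("protein_id\trank\tsequence", "p1\t1\tACDEF"), ".tsv")
  df <- read_domain_table(p)
  expect_equal(nrow(df), 1L)
  expect_equal(df$sequence, "ACDEF")

  p2 <- write_tmp(c("protein_id\trank\tsequence",
                    "p1\t2\tDDD", "p2\t1\tEEE", "p1\t1\tCCC"), ".tsv")
  df2 <- read_domain_table(p2)
  expect_equal(df2$protein_id, c("p1", "p1", "p2"))
  expect_equal(df2$rank, c(1L, 2L, 1L))
  expect_equal(df2$sequence[1], "CCC")
})

test_that("malformed domain tables are rejected", {
  dup <- write_tmp(c("protein_id\trank\tsequence", "p1\t1\tAAA", "p1\t1\tCCC"), ".tsv")
  expect_error(read_domain_table(dup), "duplicate")
  nocol <- write_tmp(c("protein_id\tsequence", "p1\tAAA"), ".tsv")
  expect_error(read_domain_table(nocol), "rank")
})

test_that("annotation tables split semicolon-separated GO ids", {
  p <- write_tmp(c("protein_id\tgo_terms", "p1\tGO:0000001;GO:0000002", "p2\t"), ".tsv")
  ann <- read_annotation_table(p)
  expect_equal(ann$p1, c("GO:0000001", "GO:0000002"))
  expect_equal(ann$p2, character(0))
})

test_that("OBO parsing keeps non-obsolete molecular_function terms only", {
  dag <- parse_obo_subset(toy_obo())
  expect_s3_class(dag, "go_dag")
  expect_setequal(dag$nodes, c("GO:0003674", "GO:0000001", "GO:0000002",
                               "GO:0000003", "GO:0000009"))
  expect_false("GO:0000007" %in% dag$nodes)  # obsolete
  expect_false("GO:0000008" %in% dag$nodes)  # other namespace
  expect_equal(dag$parents[["GO:0000002"]], "GO:0000001")
})

test_that("OBO cycles and dangling is_a targets are reported", {
  cyc <- write_tmp(c(
    "[Term]", "id: GO:0003674", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000001", "namespace: molecular_function",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000002", "namespace: molecular_function",
    "is_a: GO:0000001"), ".obo")
  expect_error(parse_obo_subset(cyc), "cycle")

  dangling <- write_tmp(c(
    "[Term]", "id: GO:0003674", "namespace: molecular_function", "",
    "[Term]", "id: GO:0000001", "namespace: molecular_function",
    "is_a: GO:9999999"), ".obo")
  expect_error(parse_obo_subset(dangling), "GO:9999999")
})

test_that("annotation propagation follows is_a chains and drops the root", {
  dag <- parse_obo_subset(toy_obo())
  # chain: 3 -> 2 -> 1 -> root
  expect_equal(propagate_annotations("GO:0000003", dag),
               c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(propagate_annotations(c("GO:0000001", "GO:0000002"), dag),
               c("GO:0000001", "GO:0000002"))
  # a term whose only parent is the root maps to itself
  expect_equal(propagate_annotations("GO:0000009", dag), "GO:0000009")
  expect_error(propagate_annotations("GO:1111111", dag), "GO:1111111")
})

test_that("propagation is idempotent and monotone", {
  dag <- parse_obo_subset(toy_obo())
  universe <- setdiff(dag$nodes, dag$root)
  set.seed(42)
  for (i in 1:20) {
    s <- sample(universe, sample(length(universe), 1))
    ps <- propagate_annotations(s, dag)
    expect_identical(propagate_annotations(ps, dag), ps)
    t_set <- union(s, sample(universe, 1))
    expect_true(all(ps %in% propagate_annotations(t_set, dag)))
  }
})

test_that("datasets are assembled with sorted labels and input-ordered rows", {
  bags <- list(new_bag("p1", matrix(1, 1, 2)), new_bag("p2", matrix(2, 1, 2)))
  ds <- build_dataset(bags, list(p1 = "g1", p2 = c("g1", "g2")))
  expect_equal(unname(ds$Y), matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(colnames(ds$Y), c("g1", "g2"))
  expect_equal(rownames(ds$Y), c("p1", "p2"))

  expect_error(build_dataset(bags, list(p1 = character(0), p2 = character(0))),
               "no labels")
  expect_error(build_dataset(bags, list(p1 = "g1", p3 = "g1", p2 = "g2")), "p3")

  # an explicit label space keeps zero columns only in observed matrices
  obs <- build_dataset(bags, list(p1 = "g1", p2 = "g1"),
                       label_space = c("g1", "gX"), role = "observed")
  expect_equal(colnames(obs$Y), c("g1", "gX"))
  expect_equal(sum(obs$Y[, "gX"]), 0)
  full <- build_dataset(bags, list(p1 = "g1", p2 = "g1"),
                        label_space = c("g1", "gX"), role = "full")
  expect_equal(colnames(full$Y), "g1")
})

test_that("the GO root is never emitted as a label", {
  bags <- list(new_bag("p1", matrix(1, 1, 2)))
  ds <- build_dataset(bags, list(p1 = c("GO:0003674", "g1")))
  expect_equal(colnames(ds$Y), "g1")
})

test_that("dataset JSON round-trip is the identity", {
  gen <- generate_dataset(synthetic_spec(m = 8, L = 6, dim = 5, seed = 2))
  path <- tempfile(fileext = ".json")
  write_dataset(gen$dataset, path)
  back <- read_dataset(path)
  expect_equal(back, gen$dataset)
})

test_that("dataset loading validates schema version and invariants", {
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = "0.9"), bad, auto_unbox = TRUE)
  expect_error(read_dataset(bad), "schema version")

  empty_bag <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    schema_version = "1.0",
    label_space = list("g1"),
    labels = list(role = "full", values = list(list(1))),
    bags = list(list(bag_id = "p1", instances = list()))),
    empty_bag, auto_unbox = TRUE)
  expect_error(read_dataset(empty_bag), "p1")
})

test_that("the shipped toy fixtures assemble into a featurized dataset", {
  ext <- function(f) system.file("extdata", f, package = "mimlwel")
  fa <- read_fasta(ext("toy_proteins.fasta"))
  expect_equal(fa$id, c("prot1", "prot2", "prot3"))
  dom <- read_domain_table(ext("toy_domains.tsv"))
  ann <- read_annotation_table(ext("toy_annotations.tsv"))
  dag <- parse_obo_subset(ext("toy_ontology.obo"))
  bags <- featurize_proteins(dom)
  ann <- lapply(ann, propagate_annotations, dag = dag)
  ds <- build_dataset(bags, ann)
  expect_equal(length(ds$bags), 3L)
  expect_setequal(colnames(ds$Y),
                  c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000009"))
  expect_equal(unname(ds$Y["prot3", c("GO:0000001", "GO:0000002")]), c(1, 1))
})
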