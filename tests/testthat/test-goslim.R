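# a 7-term OBO with a diamond: leafD -> (midA, midB) -> root, where midA is
# in the slim and midB's parent slimB is too
toy_obo_lines <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: root",
  "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: slimA",
  "namespace: biological_process", "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000003", "name: slimB",
  "namespace: biological_process", "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000004", "name: midB",
  "namespace: biological_process", "is_a: GO:0000003", "",
  "[Term]", "id: GO:0000005", "name: leafD",
  "namespace: biological_process", "is_a: GO:0000002",
  "is_a: GO:0000004", "",
  "[Term]", "id: GO:0000006", "name: obsolete_term",
  "namespace: biological_process", "is_a: GO:0000001",
  "is_obsolete: true", "",
  "[Term]", "id: GO:0000007", "name: alias_holder",
  "namespace: biological_process", "alt_id: GO:0000099",
  "is_a: GO:0000002", "")

local_obo <- function(lines = toy_obo_lines(), env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = env)
  writeLines(lines, path)
  path
}

test_that("OBO parsing excludes obsoletes and resolves alt_ids", {
  dag <- load_obo(local_obo())
  expect_equal(length(dag$parents), 6L)           # obsolete term dropped
  expect_false("GO:0000006" %in% names(dag$parents))
  expect_equal(map_to_slim("GO:0000099", "GO:0000002", dag),
               "GO:0000002")                      # alt_id -> primary -> self
  expect_error(load_obo(local_obo(c("format-version: 1.2"))), "no \\[Term\\]")
})

test_that("cyclic is_a chains are rejected", {
  bad <- c("format-version: 1.2", "",
           "[Term]", "id: GO:1", "name: a", "is_a: GO:2", "",
           "[Term]", "id: GO:2", "name: b", "is_a: GO:1", "")
  expect_error(load_obo(local_obo(bad)), "cycle")
})

test_that("slim mapping returns the term itself, direct slim parents, and diamond antichains", {
  dag <- load_obo(local_obo())
  slim <- c("GO:0000002", "GO:0000003")
  expect_equal(map_to_slim("GO:0000002", slim, dag), "GO:0000002")
  expect_equal(map_to_slim("GO:0000004", slim, dag), "GO:0000003")
  # diamond: leafD reaches slimA directly and slimB via midB; both are
  # minimal (incomparable), so both are returned
  expect_equal(map_to_slim("GO:0000005", slim, dag),
               c("GO:0000002", "GO:0000003"))
  expect_error(map_to_slim("GO:9999999", slim, dag), "not in DAG")
})

test_that("slim mapping never returns a term that is an ancestor of another returned term", {
  dag <- load_obo(local_obo())
  # root is in the slim but slimA/slimB lie between it and the leaves
  slim <- c("GO:0000001", "GO:0000002", "GO:0000003")
  got <- map_to_slim("GO:0000005", slim, dag)
  expect_equal(got, c("GO:0000002", "GO:0000003"))  # root masked
})

test_that("slim mapping matches exhaustive path enumeration on random DAGs", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    ids <- sprintf("GO:%07d", seq_len(n))
    # random DAG: each non-root node gets 1-2 parents among earlier nodes
    parents <- list()
    parents[[ids[1]]] <- character(0)
    for (i in 2:n)
      parents[[ids[i]]] <-
        ids[sample(seq_len(i - 1L), min(i - 1L, sample(1:2, 1)))]
    lines <- c("format-version: 1.2", "")
    for (i in seq_len(n)) {
      lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
                 paste0("name: t", i), "namespace: biological_process",
                 paste0("is_a: ", parents[[ids[i]]]), "")
    }
    dag <- load_obo(local_obo(lines))
    slim <- sample(ids, sample(2:4, 1))
    for (term in sample(ids, 5)) {
      expect_equal(map_to_slim(term, slim, dag),
                   oracle_slim(term, slim, parents),
                   info = paste("rep", rep, "term", term))
    }
  }
})

test_that("GOslim abundance duplicates full group counts across slim terms", {
  dag <- load_obo(local_obo())
  slim <- c("GO:0000002", "GO:0000003")
  groups <- data.frame(group_id = 1:3, anchor = c("A1", "A2", "A3"),
                       n_peptides = 1L,
                       spectral_count = c(7L, 5L, 2L),
                       bin = c("microbiome", "microbiome", "host"),
                       stringsAsFactors = FALSE)
  groups$members <- list("A1", "A2", "A3")
  ann <- list(A1 = "GO:0000005",       # diamond leaf -> both slims
              A2 = "GO:0000004",       # -> slimB only
              A3 = "GO:0000002")       # host bin: must be ignored
  prof <- goslim_abundance(groups, ann, slim, dag)
  expect_equal(prof$spectral_count[prof$slim_id == "GO:0000002"], 7L)
  expect_equal(prof$spectral_count[prof$slim_id == "GO:0000003"], 12L)
  # counts are whole group counts, never fractions
  expect_true(all(prof$spectral_count == floor(prof$spectral_count)))
})

test_that("unannotated groups and unknown GO ids are reported, empty bins give empty profiles", {
  dag <- load_obo(local_obo())
  slim <- c("GO:0000002", "GO:0000003")
  groups <- data.frame(group_id = 1:2, anchor = c("A1", "A2"),
                       n_peptides = 1L, spectral_count = c(3L, 4L),
                       bin = "microbiome", stringsAsFactors = FALSE)
  groups$members <- list("A1", "A2")
  ann <- list(A1 = "GO:7777777")       # not in the DAG
  expect_warning(prof <- goslim_abundance(groups, ann, slim, dag),
                 "absent from DAG")
  expect_equal(attr(prof, "skipped_annotations"), "GO:7777777")
  expect_equal(attr(prof, "unannotated_groups"), "A2")
  expect_equal(nrow(prof), 0L)

  none <- goslim_abundance(groups[0, ], ann, slim, dag)
  expect_equal(nrow(none), 0L)
})

test_that("anchor annotation wins, member union is the fallback", {
  dag <- load_obo(local_obo())
  slim <- c("GO:0000002", "GO:0000003")
  groups <- data.frame(group_id = 1L, anchor = "A1", n_peptides = 1L,
                       spectral_count = 6L, bin = "microbiome",
                       stringsAsFactors = FALSE)
  groups$members <- list(c("A1", "A2"))
  # anchor unannotated -> union over members supplies A2's term
  prof <- goslim_abundance(groups, list(A2 = "GO:0000004"), slim, dag)
  expect_equal(prof$spectral_count[prof$slim_id == "GO:0000003"], 6L)
})
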