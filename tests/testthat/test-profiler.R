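make_psms <- function(peptide, spectrum_id, accessions, decoy = FALSE) {
  n <- length(peptide)
  df <- data.frame(spectrum_id = spectrum_id, peptide = peptide,
                   ion_score = rep(50, n), expectation = rep(0.01, n),
                   is_decoy = rep(decoy, length.out = n),
                   stringsAsFactors = FALSE)
  df$accessions <- accessions
  df
}

fixture_map <- c(A14 = 14L, B14 = 14L, A15 = 15L, A22 = 22L)

test_that("peptide-taxa mapping unions accessions and collapses I/L variants", {
  tree <- load_taxonomy(fixture_tree_df())
  psms <- make_psms(c("PEPTIDEK", "PEPTLDEK", "AAAR", "AAAR"),
                    c("S1", "S2", "S3", "S4"),
                    list("A14", "A15", "A14", "A22"))
  psms$peptide <- canonicalize_peptide(psms$peptide)
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  expect_equal(sort(names(ptx)), c("AAAR", "PEPTLDEK"))  # I/L collapsed
  expect_equal(ptx[["PEPTLDEK"]], c(14L, 15L))
  expect_equal(ptx[["AAAR"]], c(14L, 22L))
})

test_that("peptides with no mappable accession land in the orphan report", {
  tree <- load_taxonomy(fixture_tree_df())
  psms <- make_psms(c("AAAK", "CCCK"), c("S1", "S2"),
                    list("A14", "ZZZ"))
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  expect_equal(attr(ptx, "orphans"), "CCCK")
  expect_false("CCCK" %in% names(ptx))
})

test_that("specificity is the collapse of the taxid set at a rank", {
  tree <- load_taxonomy(fixture_tree_df())
  psms <- make_psms(c("AAAK", "CCCK", "DDDK"), c("S1", "S2", "S3"),
                    list(c("A14", "A15"), "A14", c("A14", "A22")))
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  # two sibling species of genus 13
  expect_equal(is_specific("AAAK", "genus", ptx, tree), 13L)
  expect_true(is.na(is_specific("AAAK", "species", ptx, tree)))
  # single species: specific along its whole lineage
  expect_equal(is_specific("CCCK", "species", ptx, tree), 14L)
  expect_equal(is_specific("CCCK", "superkingdom", ptx, tree), 2L)
  # spans two superkingdoms: specific nowhere
  expect_true(is.na(is_specific("DDDK", "superkingdom", ptx, tree)))
})

test_that("direct tallies: a genus-specific peptide with 4 PSMs", {
  tree <- load_taxonomy(fixture_tree_df())
  psms <- make_psms(rep("AAAK", 4), paste0("S", 1:4),
                    rep(list(c("A14", "A15")), 4))
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  prof <- collate_profile(psms, ptx, tree)
  g <- prof[prof$taxid == 13 & prof$rank == "genus", ]
  expect_equal(g$specific_tsm_count, 4L)
  expect_equal(g$specific_peptide_count, 1L)
  # species rows carry the TSMs but no specificity
  s <- prof[prof$taxid == 14 & prof$rank == "species", ]
  expect_equal(s$tsm_count, 4L)
  expect_equal(s$specific_tsm_count, 0L)
})

test_that("sibling species' specific TSMs aggregate at the genus", {
  tree <- load_taxonomy(fixture_tree_df())
  psms <- make_psms(c("AAAK", "AAAK", "CCCK", "CCCK"), paste0("S", 1:4),
                    list("A14", "A14", "A15", "A15"))
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  prof <- collate_profile(psms, ptx, tree)
  g <- prof[prof$taxid == 13 & prof$rank == "genus", ]
  expect_gte(g$specific_tsm_count, 4L)
})

test_that("empty PSM input yields an empty profile", {
  tree <- load_taxonomy(fixture_tree_df())
  psms <- make_psms(character(0), character(0), list())
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  prof <- collate_profile(psms, ptx, tree)
  expect_equal(nrow(prof), 0L)
})

test_that("all four counters match the brute-force recount on random fixtures", {
  tree_df <- fixture_tree_df()
  tree <- load_taxonomy(tree_df)
  accs <- names(fixture_map)
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(50:200, 1)
    peps <- paste0("PEP", sample(1:25, n, replace = TRUE), "K")
    acc_sets <- lapply(seq_len(n), function(i)
      sample(accs, sample(1:3, 1)))
    psms <- make_psms(peps, sprintf("S%03d", seq_len(n)), acc_sets)
    # the peptide -> accession union must be consistent across PSMs
    pep_acc <- lapply(split(unlist(acc_sets, use.names = FALSE),
                            rep(peps, lengths(acc_sets))), unique)
    psms$accessions <- pep_acc[psms$peptide]
    ptx <- build_peptide_taxa(psms, fixture_map, tree)
    prof <- collate_profile(psms, ptx, tree)
    pep2tax <- lapply(pep_acc, function(a)
      sort(unique(unname(fixture_map[a]))))
    oracle <- oracle_profile(psms, pep2tax, tree_df, canonical_ranks())
    got <- as.data.frame(prof)[, names(oracle)]
    expect_equal(got, oracle, ignore_attr = TRUE)
  }
})

test_that("specific TSMs at any rank never exceed the accepted PSM total", {
  tree <- load_taxonomy(fixture_tree_df())
  set.seed(5)
  n <- 120
  peps <- paste0("Q", sample(1:15, n, replace = TRUE), "R")
  acc_sets <- lapply(seq_len(n), function(i)
    sample(names(fixture_map), sample(1:2, 1)))
  pep_acc <- lapply(split(unlist(acc_sets, use.names = FALSE),
                          rep(peps, lengths(acc_sets))), unique)
  psms <- make_psms(peps, sprintf("S%03d", 1:n), pep_acc[peps])
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  prof <- collate_profile(psms, ptx, tree)
  for (r in canonical_ranks()) {
    expect_lte(sum(prof$specific_tsm_count[prof$rank == r]), n)
  }
  # monotone collation: genus-specific >= any contained species' specific
  g <- prof[prof$rank == "genus" & prof$taxid == 13, "specific_tsm_count"]
  for (sp in c(14L, 15L)) {
    s <- prof[prof$rank == "species" & prof$taxid == sp,
              "specific_tsm_count"]
    if (length(s) && length(g)) expect_gte(g, s)
  }
})

test_that("biomass shares are proportions that sum to one", {
  tree <- load_taxonomy(fixture_tree_df())
  psms <- make_psms(c(rep("AAAK", 3), "CCCK"), paste0("S", 1:4),
                    list("A14", "A14", "A14", "A22"))
  ptx <- build_peptide_taxa(psms, fixture_map, tree)
  prof <- collate_profile(psms, ptx, tree)
  b <- biomass_shares(prof, "species")
  expect_equal(sum(b$share), 1)
  expect_equal(b$share[b$taxid == 14], 0.75)
  expect_equal(b$share[b$taxid == 22], 0.25)
  single <- biomass_shares(prof, "genus")   # only genus 13 has a genus row
  expect_equal(single$share, 1)
  empty <- collate_profile(psms[0, ], ptx, tree)
  expect_error(biomass_shares(empty, "genus"), "undefined|no specific")
})
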