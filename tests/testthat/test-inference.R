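test_that("proteins sharing a peptide are grouped; disjoint ones are not", {
  g <- group_proteins(list(a = "P1", b = c("P1", "P2"), c = "P2"))
  expect_equal(nrow(g), 1L)
  expect_setequal(g$members[[1]], c("P1", "P2"))

  g2 <- group_proteins(list(a = "P1", b = "P2"))
  expect_equal(nrow(g2), 2L)
})

test_that("subset proteins are subsumed under the maximal member", {
  g <- group_proteins(list(a = c("P1", "P2"), b = "P1"))
  expect_equal(nrow(g), 1L)
  expect_setequal(g$members[[1]], c("P1", "P2"))
  expect_equal(g$retained[[1]], "P1")      # P2 = {a} subset of P1 = {a,b}
  expect_equal(g$anchor, "P1")
})

test_that("parsimony collapse equals exhaustive minimal cover on fragment instances", {
  set.seed(17)
  for (rep in 1:15) {
    # construct true proteins with disjoint peptide sets, then add
    # fragment proteins whose peptides are subsets of one true protein:
    # the unique minimum cover is the set of true proteins
    n_true <- sample(2:4, 1)
    peps <- split(paste0("pep", 1:12),
                  rep(seq_len(n_true), length.out = 12))
    prot_peps <- stats::setNames(peps, paste0("T", seq_len(n_true)))
    n_frag <- sample(1:6, 1)
    for (f in seq_len(n_frag)) {
      src <- sample(n_true, 1)
      take <- sample(length(prot_peps[[src]]),
                     sample(length(prot_peps[[src]]) - 1L, 1))
      prot_peps[[paste0("F", f)]] <- prot_peps[[src]][take]
    }
    pep2acc <- lapply(
      split(rep(names(prot_peps), lengths(prot_peps)),
            unlist(prot_peps, use.names = FALSE)), unique)
    groups <- group_proteins(pep2acc)
    retained <- sort(unlist(groups$retained, use.names = FALSE))
    covers <- oracle_min_covers(pep2acc)
    if (length(covers) == 1L)
      expect_equal(retained, sort(covers[[1]]))
    # regardless of uniqueness, retained proteins must explain all peptides
    expect_true(all(vapply(pep2acc, function(a) any(a %in% retained),
                           logical(1))))
  }
})

test_that("grouping is invariant to input permutation", {
  pep2acc <- list(a = c("P1", "P2"), b = c("P2", "P3"), c = "P4",
                  d = c("P4", "P5"), e = "P1")
  g1 <- group_proteins(pep2acc)
  g2 <- group_proteins(pep2acc[c(4, 2, 5, 1, 3)])
  expect_identical(g1, g2)
})

test_that("spectral counts conserve the accepted PSM total with razor assignment", {
  pep2acc <- list(a = "P1", b = c("P1", "P2"), c = "P3", d = "P4")
  groups <- group_proteins(pep2acc)     # {P1,P2}, {P3}, {P4}
  psm <- function(pep, acc, n) {
    df <- data.frame(spectrum_id = paste0(pep, seq_len(n)), peptide = pep,
                     ion_score = 50, expectation = 0.01, is_decoy = FALSE)
    df$accessions <- rep(list(acc), n)
    df
  }
  psms <- rbind(psm("a", "P1", 9), psm("c", "P3", 2),
                psm("x", c("P1", "P3"), 1))   # spans two groups
  q <- assign_spectral_counts(groups, psms)
  expect_equal(sum(q$spectral_count), nrow(psms))
  # razor: ambiguous PSM goes to the 9-count group, not the 2-count one
  expect_equal(q$spectral_count[q$anchor == "P1"], 10L)
  expect_equal(q$spectral_count[q$anchor == "P3"], 2L)

  zero <- assign_spectral_counts(groups, psms[0, ])
  expect_true(all(zero$spectral_count == 0L))
  orphanned <- psm("z", "P99", 1)
  expect_error(assign_spectral_counts(groups, orphanned), "no group")
})

test_that("razor assignment matches brute-force enumeration on a three-group fixture", {
  pep2acc <- list(a = "A", b = "B", c = "C")
  groups <- group_proteins(pep2acc)
  build <- function(spec) {
    do.call(rbind, lapply(seq_along(spec), function(i) {
      df <- data.frame(spectrum_id = paste0("s", i), peptide = "p",
                       ion_score = 50, expectation = 0.01,
                       is_decoy = FALSE)
      df$accessions <- list(spec[[i]])
      df
    }))
  }
  # 5 unambiguous to A, 2 to B, then one PSM shared A/B and one shared B/C
  psms <- build(c(rep(list("A"), 5), rep(list("B"), 2),
                  list(c("A", "B")), list(c("B", "C"))))
  q <- assign_spectral_counts(groups, psms)
  # shared A/B -> A (5 > 2); shared B/C -> B (2 > 0)
  expect_equal(q$spectral_count[q$anchor == "A"], 6L)
  expect_equal(q$spectral_count[q$anchor == "B"], 3L)
  expect_equal(q$spectral_count[q$anchor == "C"], 0L)
})

test_that("groups inherit bins; mixed groups resolve to the anchor and are flagged", {
  pep2acc <- list(a = c("H1", "M1"), b = "M2")
  groups <- group_proteins(pep2acc)
  bins <- c(H1 = "host", M1 = "microbiome", M2 = "microbiome")
  labelled <- bin_groups(groups, bins)
  mixed <- labelled[labelled$mixed_bin, ]
  expect_equal(nrow(mixed), 1L)
  expect_equal(mixed$bin, unname(bins[mixed$anchor]))
  pure <- labelled[!labelled$mixed_bin, ]
  expect_equal(pure$bin, "microbiome")
  expect_error(bin_groups(groups, bins[-1]), "no sub-database")
})

test_that("PSM-level FDR filtering keeps the largest prefix within the ratio", {
  psms <- data.frame(
    spectrum_id = paste0("s", 1:6),
    peptide = "p", ion_score = 50,
    expectation = c(0.001, 0.002, 0.003, 0.004, 0.005, 0.006),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  psms$accessions <- as.list(ifelse(psms$is_decoy, "DECOY_A", "A"))
  # at fdr=0.25: prefix through the decoy has d/t = 1/4 = 0.25 -> the
  # whole table passes and 5 targets survive
  kept <- filter_psm_fdr(psms, fdr = 0.25)
  expect_equal(nrow(kept), 5L)
  expect_false(any(kept$is_decoy))
  # at fdr=0.1 the prefix must stop before the decoy
  strict <- filter_psm_fdr(psms, fdr = 0.1)
  expect_equal(nrow(strict), 4L)
})
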