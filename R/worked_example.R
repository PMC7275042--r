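#' A fixed, hand-written worked-example world
#'
#' A tiny three-genus / six-protein / thirty-PSM world whose every
#' intermediate number is documented in the companion tables shipped under
#' \code{inst/extdata/worked_example/}. Two bacterial genera (Escherichia
#' with two species, Pseudomonas) and one fungal genus (Saccharomyces)
#' carry eight peptides; one spectrum holds multiple candidate matches to
#' exercise the 98\%-of-top-score rule, and one reversed-decoy PSM feeds
#' the taxonomic FDR estimate. Used in the documentation and in golden
#' tests.
#'
#' @param out_dir optional directory; when given, taxonomy, accession map,
#'   PSM table, proteome FASTAs, GO files and annotations are written
#'   there.
#' @return list with \code{taxonomy}, \code{acc2tax}, \code{psms},
#'   \code{proteome}, \code{sequences}, \code{go} (obo lines, slim,
#'   annotations) — same shape as \code{\link{simulate_world}} output.
#' @export
make_worked_example <- function(out_dir = NULL) {
  taxonomy <- data.frame(
    taxid = c(1L, 2L, 3L, 21L, 22L, 23L, 24L, 25L, 251L, 252L,
              33L, 34L, 35L, 351L, 39L, 41L, 42L, 43L, 44L, 45L, 451L),
    parent_taxid = c(1L, 1L, 1L, 2L, 21L, 22L, 23L, 24L, 25L, 25L,
                     22L, 33L, 34L, 35L, 3L, 39L, 41L, 42L, 43L, 44L, 45L),
    rank = c("no_rank", "superkingdom", "superkingdom", "phylum", "class",
             "order", "family", "genus", "species", "species",
             "order", "family", "genus", "species", "no_rank", "phylum",
             "class", "order", "family", "genus", "species"),
    name = c("root", "Bacteria", "Eukaryota", "Proteobacteria",
             "Gammaproteobacteria", "Enterobacterales",
             "Enterobacteriaceae", "Escherichia", "Escherichia_coli",
             "Escherichia_fergusonii", "Pseudomonadales",
             "Pseudomonadaceae", "Pseudomonas", "Pseudomonas_fluvialis",
             "Fungi", "Ascomycota", "Saccharomycetes", "Saccharomycetales",
             "Saccharomycetaceae", "Saccharomyces",
             "Saccharomyces_cerevisiae"),
    stringsAsFactors = FALSE)

  proteome <- list(
    P251_1 = c("AAAAAAK", "CCCCCCK"),
    P251_2 = "DDDDDDK",
    P252_1 = c("CCCCCCK", "EEEEEEK"),
    P351_1 = c("FFFFFFK", "GGGGGGK"),
    P351_2 = "GGGGGGK",
    P451_1 = c("HHHHHHK", "MMMMMMK"))
  acc2tax <- c(P251_1 = 251L, P251_2 = 251L, P252_1 = 252L,
               P351_1 = 351L, P351_2 = 351L, P451_1 = 451L)
  sequences <- vapply(proteome, paste, character(1), collapse = "")

  row <- function(sid, pep, score, e, acc, decoy = "false")
    data.frame(spectrum_id = sid, peptide = pep, ion_score = score,
               expectation = e, accessions = acc, is_decoy = decoy,
               stringsAsFactors = FALSE)
  psms <- do.call(rbind, c(
    lapply(sprintf("S%02d", 1:5),
           row, pep = "AAAAAAK", score = 55, e = 0.001, acc = "P251_1"),
    list(row("S06", "AAAAAAK", 100, 0.001, "P251_1"),
         row("S06", "CCCCCCK", 98.5, 0.002, "P251_1;P252_1"),
         row("S06", "FFFFFFK", 97, 0.002, "P351_1")),   # fails the 98% rule
    lapply(sprintf("S%02d", 7:9),
           row, pep = "CCCCCCK", score = 55, e = 0.001,
           acc = "P251_1;P252_1"),
    lapply(sprintf("S%02d", 10:12),
           row, pep = "DDDDDDK", score = 55, e = 0.001, acc = "P251_2"),
    lapply(sprintf("S%02d", 13:15),
           row, pep = "EEEEEEK", score = 55, e = 0.001, acc = "P252_1"),
    lapply(sprintf("S%02d", 16:20),
           row, pep = "FFFFFFK", score = 55, e = 0.001, acc = "P351_1"),
    lapply(sprintf("S%02d", 21:23),
           row, pep = "GGGGGGK", score = 55, e = 0.001,
           acc = "P351_1;P351_2"),
    lapply(sprintf("S%02d", 24:25),
           row, pep = "HHHHHHK", score = 55, e = 0.001, acc = "P451_1"),
    lapply(sprintf("S%02d", 26:27),
           row, pep = "MMMMMMK", score = 55, e = 0.001, acc = "P451_1"),
    list(row("S28", "KAAAAAA", 20, 0.03, "DECOY_P251_1", "true"))))

  go <- toy_go(character(0))
  go$annotations <- data.frame(
    accession = c("P251_1", "P251_2", "P252_1", "P351_1", "P351_2",
                  "P451_1"),
    go_id = c("GO:0006508", "GO:0006508", "GO:0006508", "GO:0042026",
              "GO:0042026", "GO:0019538"),
    stringsAsFactors = FALSE)

  world <- list(taxonomy = taxonomy, acc2tax = acc2tax, proteome = proteome,
                sequences = sequences, psms = psms, go = go)
  class(world) <- "sim_world"
  if (!is.null(out_dir)) {
    world$truth <- list(community_genera = c(25L, 35L, 45L),
                        planted_shares = c(`25` = 16 / 28, `35` = 8 / 28,
                                           `45` = 4 / 28),
                        realized_shares = c(`25` = 16 / 28, `35` = 8 / 28,
                                            `45` = 4 / 28),
                        protein_group_members =
                          peptide_sharing_components(proteome))
    write_world(world, out_dir)
  }
  world
}

#' Run the full cascade on an in-memory world
#'
#' Convenience driver used by the documentation, the golden tests and the
#' command line: validates PSMs, applies the per-spectrum acceptance rule,
#' collates the taxon profile, computes biomass shares, estimates the
#' genus-level FDR, infers quantified protein groups, bins them, and rolls
#' microbial counts up to GOslim terms.
#'
#' @param world output of \code{\link{simulate_world}} or
#'   \code{\link{make_worked_example}}.
#' @param expectation_cutoff,fraction,min_specific,rank tunables passed to
#'   the stage functions.
#' @return list with \code{profile}, \code{biomass}, \code{calls},
#'   \code{fdr}, \code{groups}, \code{goslim}, \code{accepted} (the
#'   validated spectrum set), \code{ptx}.
#' @export
run_cascade <- function(world, expectation_cutoff = 0.05, fraction = 0.98,
                        min_specific = 3L, rank = "genus") {
  tree <- load_taxonomy(world$taxonomy)
  map <- stats::setNames(unname(world$acc2tax), names(world$acc2tax))
  psms <- world$psms
  psms$accessions <- strsplit(psms$accessions, ";", fixed = TRUE)
  psms$peptide <- canonicalize_peptide(psms$peptide)
  psms$is_decoy <- tolower(psms$is_decoy) %in% c("true", "t", "1", "yes")
  accepted <- select_spectrum_psms(
    validate_psms(psms, expectation_cutoff), fraction)
  targets <- accepted[!accepted$is_decoy, , drop = FALSE]

  ptx <- build_peptide_taxa(targets, map, tree)
  profile <- collate_profile(targets, ptx, tree)
  biomass <- biomass_shares(profile, rank)

  decoy_ptx <- build_decoy_peptide_taxa(accepted, map, tree)
  calls <- call_genera(ptx, decoy_ptx, tree, min_specific)
  fdr <- estimate_taxonomic_fdr(calls)

  pep2acc <- lapply(split(unlist(targets$accessions, use.names = FALSE),
                          rep(targets$peptide,
                              lengths(targets$accessions))), unique)
  groups <- assign_spectral_counts(group_proteins(pep2acc), targets)
  part <- partition_taxa(unique(unname(map)), tree)
  bins <- accession_bins_from_partition(map, part, tree)
  bins <- c(bins, stats::setNames(bins, paste0("DECOY_", names(bins))))
  groups <- bin_groups(groups, bins)

  dag <- load_obo(textConnection(world$go$obo))
  ann <- load_go_annotations(world$go$annotations)
  goslim <- goslim_abundance(groups, ann, world$go$slim, dag)

  list(profile = profile, biomass = biomass, calls = calls, fdr = fdr,
       groups = groups, goslim = goslim, accepted = accepted, ptx = ptx)
}
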