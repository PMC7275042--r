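#' Simulation configuration for a synthetic metaproteomics world
#'
#' Defines a toy holobiont world: a small multi-superkingdom taxonomy,
#' per-species proteomes of tryptic-like peptides with controlled sharing,
#' a planted community with known biomass proportions, and PSM score /
#' expectation distributions for targets and reversed decoys. Identical
#' seeds give byte-identical worlds.
#'
#' @param seed integer RNG seed.
#' @param n_genera named integer vector: genera per superkingdom.
#' @param species_per_genus,proteins_per_species,peptides_per_protein world
#'   sizes.
#' @param community_shares numeric vector summing to 1; planted genus-level
#'   biomass proportions (recycled over the community genera in taxid
#'   order). Default 50/30/20 over three genera.
#' @param n_psms target PSMs to draw.
#' @param shared_peptide_fraction fraction of peptides copied into a
#'   sibling species of the same genus (these become genus- but not
#'   species-specific).
#' @param decoy_psm_rate decoy PSMs as a fraction of \code{n_psms}.
#' @param target_score,decoy_score lists \code{(mean, sd)} of ion scores.
#' @param target_log10e,decoy_log10e ranges of log10 expectation values.
#' @return list of class \code{sim_config}.
#' @export
simulation_config <- function(seed = 1L,
                              n_genera = c(Bacteria = 3L, Eukaryota = 1L,
                                           Archaea = 1L),
                              species_per_genus = 2L,
                              proteins_per_species = 4L,
                              peptides_per_protein = 6L,
                              community_shares = c(0.5, 0.3, 0.2),
                              n_psms = 2000L,
                              shared_peptide_fraction = 0.1,
                              decoy_psm_rate = 0.1,
                              target_score = list(mean = 60, sd = 8),
                              decoy_score = list(mean = 25, sd = 8),
                              target_log10e = c(-6, -1.4),
                              decoy_log10e = c(-1.6, 0.5)) {
  stopifnot(abs(sum(community_shares) - 1) < 1e-9,
            shared_peptide_fraction >= 0, shared_peptide_fraction <= 1,
            decoy_psm_rate >= 0, n_psms > 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

pick1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length-1 vectors

random_tryptic_peptide <- function(min_len = 7L, max_len = 25L) {
  len <- pick1(min_len:max_len)
  body <- sample(setdiff(AA20, c("I", "K", "R")), len - 1L, replace = TRUE)
  paste0(paste(body, collapse = ""), pick1(c("K", "R")))
}

reverse_peptide <- function(p)
  vapply(strsplit(p, ""), function(x) paste(rev(x), collapse = ""),
         character(1))

#' Simulate a synthetic metaproteomics world
#'
#' Builds the taxonomy, proteomes, accession map, GO toy DAG and
#' annotations, draws target PSMs from the planted community and decoy PSMs
#' from reversed sequences, and (optionally) writes every file plus the
#' ground truth to a directory in the dialects the other modules read.
#'
#' @param config a \code{sim_config}.
#' @param out_dir optional directory; when given, all fixture files are
#'   written there.
#' @return list of class \code{sim_world}: \code{taxonomy} (data.frame),
#'   \code{acc2tax}, \code{proteome} (accession -> peptide vector),
#'   \code{sequences} (accession -> protein string), \code{psms}
#'   (data.frame in the PSM-table dialect), \code{go} (obo lines, slim ids,
#'   annotation data.frame, leaf -> slim map), and \code{truth} (planted
#'   genus taxids, shares, protein-group memberships, GOslim totals).
#' @export
simulate_world <- function(config = simulation_config(), out_dir = NULL) {
  set.seed(config$seed)
  sk_names <- names(config$n_genera)

  ## ---- taxonomy: root -> superkingdoms -> (clades) -> full lineages ----
  rows <- list(data.frame(taxid = 1L, parent_taxid = 1L, rank = "no_rank",
                          name = "root", stringsAsFactors = FALSE))
  nid <- 1L
  new_node <- function(parent, rank, name) {
    nid <<- nid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      taxid = nid, parent_taxid = parent, rank = rank, name = name,
      stringsAsFactors = FALSE)
    nid
  }
  genus_ids <- integer(0); genus_sk <- character(0)
  species_ids <- list()
  for (sk in sk_names) {
    sk_id <- new_node(1L, "superkingdom", sk)
    # Eukaryota gets explicit clade nodes so partitioning has lineages to
    # test against; microbial eukaryote genera sit under Fungi
    clade_id <- sk_id
    if (sk == "Eukaryota") {
      new_node(sk_id, "no_rank", "Metazoa")
      new_node(sk_id, "no_rank", "Streptophyta")
      clade_id <- new_node(sk_id, "no_rank", "Fungi")
    }
    for (g in seq_len(config$n_genera[[sk]])) {
      stem <- paste0(substr(sk, 1, 3), g)
      ph <- new_node(clade_id, "phylum", paste0(stem, "_phylum"))
      cl <- new_node(ph, "class", paste0(stem, "_class"))
      or <- new_node(cl, "order", paste0(stem, "_order"))
      fa <- new_node(or, "family", paste0(stem, "_family"))
      ge <- new_node(fa, "genus", paste0(stem, "_genus"))
      genus_ids <- c(genus_ids, ge); genus_sk <- c(genus_sk, sk)
      sp <- integer(0)
      for (s in seq_len(config$species_per_genus))
        sp <- c(sp, new_node(ge, "species", paste0(stem, "_sp", s)))
      species_ids[[as.character(ge)]] <- sp
    }
  }
  taxonomy <- do.call(rbind, rows)

  ## ---- proteomes with controlled peptide sharing ----
  proteome <- list()      # accession -> peptide vector
  acc2tax <- integer(0)
  used_peptides <- new.env(parent = emptyenv())
  fresh_peptide <- function() {
    repeat {
      p <- random_tryptic_peptide()
      if (is.null(used_peptides[[p]])) { used_peptides[[p]] <- TRUE
        return(p) }
    }
  }
  for (ge in names(species_ids)) {
    for (sp in species_ids[[ge]]) {
      for (k in seq_len(config$proteins_per_species)) {
        acc <- sprintf("P%d_%d", sp, k)
        proteome[[acc]] <- vapply(seq_len(config$peptides_per_protein),
                                  function(i) fresh_peptide(), character(1))
        acc2tax[acc] <- sp
      }
    }
  }
  # copy a fraction of peptides into a sibling species (same genus):
  # those peptides stay genus-specific but lose species specificity
  for (ge in names(species_ids)) {
    sps <- species_ids[[ge]]
    if (length(sps) < 2L) next
    for (sp in sps) {
      accs <- names(acc2tax)[acc2tax == sp]
      peps <- unlist(proteome[accs], use.names = FALSE)
      n_share <- round(config$shared_peptide_fraction * length(peps))
      if (n_share == 0L) next
      shared <- sample(peps, n_share)
      sib <- pick1(setdiff(sps, sp))
      sib_acc <- pick1(names(acc2tax)[acc2tax == sib])
      proteome[[sib_acc]] <- unique(c(proteome[[sib_acc]], shared))
    }
  }
  sequences <- vapply(proteome, paste, character(1), collapse = "")

  ## ---- planted community over the first superkingdom's genera ----
  shares <- config$community_shares
  community <- genus_ids[seq_along(shares)]
  names(shares) <- community

  ## ---- target PSMs ----
  n <- config$n_psms
  species_peps <- lapply(
    stats::setNames(nm = as.character(unlist(species_ids))),
    function(sp) unique(unlist(
      proteome[names(acc2tax)[acc2tax == as.integer(sp)]],
      use.names = FALSE)))
  pep_owner <- split(rep(names(proteome), lengths(proteome)),
                     unlist(proteome, use.names = FALSE))
  g_draw <- community[sample.int(length(community), n, replace = TRUE,
                                 prob = shares)]
  psm_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- pick1(species_ids[[as.character(g_draw[i])]])
    pep <- pick1(species_peps[[as.character(sp)]])
    psm_rows[[i]] <- data.frame(
      spectrum_id = sprintf("S%06d", i),
      peptide = pep,
      ion_score = max(1, stats::rnorm(1, config$target_score$mean,
                                      config$target_score$sd)),
      expectation = 10^stats::runif(1, config$target_log10e[1],
                                    config$target_log10e[2]),
      accessions = paste(sort(pep_owner[[pep]]), collapse = ";"),
      is_decoy = "false", stringsAsFactors = FALSE)
  }
  ## ---- decoy PSMs from reversed sequences ----
  n_dec <- round(config$decoy_psm_rate * n)
  dec_rows <- vector("list", n_dec)
  all_accs <- names(proteome)
  for (i in seq_len(n_dec)) {
    acc <- pick1(all_accs)
    pep <- reverse_peptide(pick1(proteome[[acc]]))
    dec_rows[[i]] <- data.frame(
      spectrum_id = sprintf("D%06d", i),
      peptide = pep,
      ion_score = max(1, stats::rnorm(1, config$decoy_score$mean,
                                      config$decoy_score$sd)),
      expectation = 10^stats::runif(1, config$decoy_log10e[1],
                                    config$decoy_log10e[2]),
      accessions = paste0("DECOY_", acc),
      is_decoy = "true", stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, c(psm_rows, dec_rows))

  ## ---- toy GO DAG, slim, annotations ----
  go <- toy_go(names(proteome), seed_offset = config$seed)

  ## ---- ground truth ----
  true_shares <- as.numeric(table(factor(g_draw, levels = community)) / n)
  truth <- list(
    community_genera = community,
    planted_shares = stats::setNames(as.numeric(shares), community),
    realized_shares = stats::setNames(true_shares, community),
    protein_group_members = peptide_sharing_components(proteome),
    goslim_totals = NULL)   # depends on counts; filled by consumers

  world <- list(taxonomy = taxonomy, acc2tax = acc2tax,
                proteome = proteome, sequences = sequences, psms = psms,
                go = go, truth = truth, config = config)
  class(world) <- "sim_world"
  if (!is.null(out_dir)) write_world(world, out_dir)
  world
}

# connected components of the protein / shared-peptide incidence, computed
# at generation time by iterated merging (generator-side bookkeeping)
peptide_sharing_components <- function(proteome) {
  comp <- stats::setNames(seq_along(proteome), names(proteome))
  pep_owner <- split(rep(names(proteome), lengths(proteome)),
                     unlist(proteome, use.names = FALSE))
  repeat {
    changed <- FALSE
    for (owners in pep_owner) {
      if (length(owners) < 2L) next
      m <- min(comp[owners])
      if (any(comp[owners] != m)) {
        comp[comp %in% comp[owners]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(names(comp), comp), sort))
}

# small GO DAG: one namespace, two slim branches under the root, leaves
# annotated to proteins round-robin; leaf -> minimal-slim map recorded
toy_go <- function(accessions, seed_offset = 0L) {
  terms <- c(root = "GO:0008150", slimA = "GO:0008152",
             slimB = "GO:0006950", leafA = "GO:0006508",
             leafB = "GO:0042026", leafAB = "GO:0019538")
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0008152", "name: metabolic process",
    "namespace: biological_process", "is_a: GO:0008150", "",
    "[Term]", "id: GO:0006950", "name: response to stress",
    "namespace: biological_process", "is_a: GO:0008150", "",
    "[Term]", "id: GO:0006508", "name: proteolysis",
    "namespace: biological_process", "is_a: GO:0008152", "",
    "[Term]", "id: GO:0042026", "name: protein refolding",
    "namespace: biological_process", "is_a: GO:0006950", "",
    "[Term]", "id: GO:0019538", "name: protein metabolic process",
    "namespace: biological_process", "is_a: GO:0008152",
    "is_a: GO:0006950", "")
  slim <- c("GO:0008152", "GO:0006950")
  leaf_slims <- list("GO:0006508" = "GO:0008152",
                     "GO:0042026" = "GO:0006950",
                     "GO:0019538" = c("GO:0006950", "GO:0008152"))
  leaves <- names(leaf_slims)
  ann <- data.frame(accession = accessions,
                    go_id = leaves[(seq_along(accessions) - 1L) %%
                                     length(leaves) + 1L],
                    stringsAsFactors = FALSE)
  list(obo = obo, slim = slim, annotations = ann, leaf_slims = leaf_slims)
}

#' Write a simulated world to fixture files
#'
#' Emits \code{taxonomy.tsv}, \code{acc2tax.tsv}, \code{psms.tsv}, one
#' \code{<taxid>.faa} per species under \code{proteomes/}, \code{go.obo},
#' \code{goslim.txt}, \code{annotations.tsv} and
#' \code{ground_truth.json}.
#'
#' @param world a \code{sim_world}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(world$taxonomy, "taxonomy.tsv")
  wt(data.frame(accession = names(world$acc2tax),
                taxid = unname(world$acc2tax)), "acc2tax.tsv")
  wt(world$psms, "psms.tsv")
  fd <- file.path(dir, "proteomes")
  dir.create(fd, showWarnings = FALSE)
  for (sp in unique(world$acc2tax)) {
    accs <- names(world$acc2tax)[world$acc2tax == sp]
    seqs <- Biostrings::AAStringSet(world$sequences[accs])
    Biostrings::writeXStringSet(seqs, file.path(fd, paste0(sp, ".faa")))
  }
  writeLines(world$go$obo, file.path(dir, "go.obo"))
  writeLines(world$go$slim, file.path(dir, "goslim.txt"))
  wt(world$go$annotations, "annotations.tsv")
  jsonlite::write_json(
    list(community_genera = world$truth$community_genera,
         planted_shares = world$truth$planted_shares,
         realized_shares = world$truth$realized_shares,
         protein_group_members = world$truth$protein_group_members),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Simulate a feature-by-sample abundance matrix with planted shifts
#'
#' Negative-binomial counts for two groups with a multiplicative shift
#' planted in the first \code{n_shifted} features; used to exercise the
#' differential layer with known ground truth.
#'
#' @param n_features,n_per_group matrix dimensions.
#' @param n_shifted number of planted differential features.
#' @param fold multiplicative shift in group 2.
#' @param base_mean,dispersion negative-binomial mean and size; the default
#'   size of 20 gives the moderate extra-Poisson spread typical of
#'   spectral-count replicates.
#' @param seed RNG seed.
#' @return list \code{counts} (matrix), \code{groups}, \code{shifted}
#'   (logical ground truth per feature).
#' @export
simulate_abundance_matrix <- function(n_features = 50L, n_per_group = 6L,
                                      n_shifted = 5L, fold = 4,
                                      base_mean = 100, dispersion = 20,
                                      seed = 1L) {
  set.seed(seed)
  mu <- matrix(base_mean, n_features, 2L * n_per_group)
  mu[seq_len(n_shifted), n_per_group + seq_len(n_per_group)] <-
    base_mean * fold
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                   n_features, 2L * n_per_group)
  rownames(counts) <- sprintf("F%03d", seq_len(n_features))
  colnames(counts) <- c(sprintf("A%d", seq_len(n_per_group)),
                        sprintf("B%d", seq_len(n_per_group)))
  list(counts = counts,
       groups = rep(c("A", "B"), each = n_per_group),
       shifted = seq_len(n_features) <= n_shifted)
}
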