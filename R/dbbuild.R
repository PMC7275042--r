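#' Superkingdom-specific species retention policy
#'
#' Thresholds are exclusive ("more than"): a species is retained when its
#' specific-peptide count exceeds \code{min_specific_peptides} OR its TSM
#' count exceeds \code{min_tsms} for its superkingdom. Defaults follow the
#' cascade's step-2 settings: eukaryota (9, 109), bacteria (7, 74),
#' archaea (1, 6).
#'
#' @param eukaryota,bacteria,archaea integer pairs
#'   \code{c(min_specific_peptides, min_tsms)}.
#' @return data.frame policy, one row per superkingdom.
#' @export
retention_policy <- function(eukaryota = c(9L, 109L),
                             bacteria = c(7L, 74L),
                             archaea = c(1L, 6L)) {
  pol <- data.frame(
    superkingdom = c("Eukaryota", "Bacteria", "Archaea"),
    min_specific_peptides = c(eukaryota[1], bacteria[1], archaea[1]),
    min_tsms = c(eukaryota[2], bacteria[2], archaea[2]),
    stringsAsFactors = FALSE)
  stopifnot(all(pol$min_specific_peptides >= 0), all(pol$min_tsms >= 0))
  pol
}

#' Retain species for the step-2 sub-databases
#'
#' Applies the retention policy to the species rows of a taxon profile.
#' The specific-peptide clause uses \code{specific_peptide_count}; the TSM
#' clause uses total \code{tsm_count} at species rank.
#'
#' @param profile a \code{taxon_profile}.
#' @param tree \code{taxonomy_tree} (for superkingdom projection).
#' @param policy data.frame from \code{\link{retention_policy}}.
#' @return data.frame of retained species: \code{taxid, name, superkingdom,
#'   specific_peptide_count, tsm_count, reason} where reason is
#'   \code{"specific_peptides"}, \code{"tsms"} or \code{"both"}.
#' @export
retain_species <- function(profile, tree, policy = retention_policy()) {
  sp <- profile[profile$rank == "species", , drop = FALSE]
  if (nrow(sp) == 0L)
    return(data.frame(taxid = integer(0), name = character(0),
                      superkingdom = character(0),
                      specific_peptide_count = integer(0),
                      tsm_count = integer(0), reason = character(0),
                      stringsAsFactors = FALSE))
  sk_tax <- project_to_rank(tree, sp$taxid, "superkingdom")
  if (anyNA(sk_tax))
    stop("species with no superkingdom projection: ",
         paste(sp$taxid[is.na(sk_tax)], collapse = ", "))
  sk <- tax_name(tree, sk_tax)
  missing_pol <- setdiff(unique(sk), policy$superkingdom)
  if (length(missing_pol))
    stop("retention policy does not cover superkingdom(s): ",
         paste(missing_pol, collapse = ", "))
  i <- match(sk, policy$superkingdom)
  by_pep <- sp$specific_peptide_count > policy$min_specific_peptides[i]
  by_tsm <- sp$tsm_count > policy$min_tsms[i]
  keep <- by_pep | by_tsm
  reason <- ifelse(by_pep & by_tsm, "both",
                   ifelse(by_pep, "specific_peptides", "tsms"))
  out <- data.frame(taxid = sp$taxid, name = sp$name, superkingdom = sk,
                    specific_peptide_count = sp$specific_peptide_count,
                    tsm_count = sp$tsm_count, reason = reason,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy representative-taxon selection
#'
#' Candidates are sorted by total TSM count (spectra covered) descending,
#' ties broken by ascending taxid; walking that order, a candidate is
#' accepted when it covers at least \code{min_added} spectra not covered by
#' previously accepted representatives, stopping at \code{max_taxa}.
#'
#' @param coverage named list: taxid (as name) -> character vector of
#'   spectrum ids the candidate covers.
#' @param max_taxa maximum representatives (default 10).
#' @param min_added minimum newly covered spectra per acceptance (default 2).
#' @return data.frame \code{taxid, tsm_count, added_tsms} in acceptance
#'   order.
#' @export
select_representatives <- function(coverage, max_taxa = 10L, min_added = 2L) {
  taxid <- as.integer(names(coverage))
  n_cov <- lengths(lapply(coverage, unique))
  ord <- order(-n_cov, taxid)
  covered <- character(0)
  acc <- list()
  for (k in ord) {
    if (length(acc) >= max_taxa) break
    new_spectra <- setdiff(unique(coverage[[k]]), covered)
    if (length(new_spectra) >= min_added) {
      acc[[length(acc) + 1L]] <- data.frame(
        taxid = taxid[k], tsm_count = n_cov[[k]],
        added_tsms = length(new_spectra))
      covered <- c(covered, new_spectra)
    }
  }
  if (length(acc) == 0L)
    return(data.frame(taxid = integer(0), tsm_count = integer(0),
                      added_tsms = integer(0)))
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

#' Partition retained taxa into the three sub-database bins
#'
#' Metazoa go to the host bin (they complement the host transcriptome
#' database), Streptophyta — the remaining multicellular eukaryotes — to the
#' food bin, and everything else (unicellular eukaryotes, bacteria, archaea)
#' to the unicellular bin. Membership is decided by lineage under the clade
#' nodes named \code{Metazoa} / \code{Streptophyta} (overridable by taxid).
#'
#' @param taxids retained species taxids.
#' @param tree \code{taxonomy_tree}.
#' @param metazoa_taxid,streptophyta_taxid clade roots; by default the nodes
#'   with those names are looked up in the tree (absent clades are treated
#'   as empty).
#' @return named list of integer vectors: \code{host_metazoa},
#'   \code{streptophyta}, \code{unicellular}; a disjoint cover of
#'   \code{taxids}.
#' @export
partition_taxa <- function(taxids, tree,
                           metazoa_taxid = NULL, streptophyta_taxid = NULL) {
  find_clade <- function(given, nm) {
    if (!is.null(given)) return(given)
    hit <- tree$taxid[tree$name == nm]
    if (length(hit) == 1L) hit else NA_integer_
  }
  mz <- find_clade(metazoa_taxid, "Metazoa")
  st <- find_clade(streptophyta_taxid, "Streptophyta")
  in_mz <- if (is.na(mz)) rep(FALSE, length(taxids)) else
    is_ancestor(tree, mz, taxids)
  in_st <- if (is.na(st)) rep(FALSE, length(taxids)) else
    is_ancestor(tree, st, taxids)
  list(host_metazoa = taxids[in_mz],
       streptophyta = taxids[!in_mz & in_st],
       unicellular = taxids[!in_mz & !in_st])
}

#' Per-accession bin labels from a sub-database partition
#'
#' Translates the three sub-database bins into the protein-group bin
#' vocabulary: \code{host_metazoa} -> \code{host}, \code{streptophyta} ->
#' \code{food}, \code{unicellular} -> \code{microbiome}.
#'
#' @param map accession->taxid map.
#' @param partition output of \code{\link{partition_taxa}}.
#' @param tree \code{taxonomy_tree}; accessions of species under a
#'   partitioned taxid are binned with it.
#' @return named character vector: accession -> bin label.
#' @export
accession_bins_from_partition <- function(map, partition, tree) {
  bin_of <- function(taxid) {
    if (any(vapply(partition$host_metazoa, is_ancestor, logical(1),
                   tree = tree, taxid = taxid))) return("host")
    if (any(vapply(partition$streptophyta, is_ancestor, logical(1),
                   tree = tree, taxid = taxid))) return("food")
    if (any(vapply(partition$unicellular, is_ancestor, logical(1),
                   tree = tree, taxid = taxid))) return("microbiome")
    NA_character_
  }
  bins <- vapply(unique(unname(map)), bin_of, character(1))
  names(bins) <- unique(unname(map))
  out <- bins[as.character(unname(map))]
  names(out) <- names(map)
  out
}

#' Write a tailored sub-database FASTA (with optional reversed decoys)
#'
#' Concatenates the proteomes of the representative taxa (one FASTA per
#' taxid, \code{<taxid>.faa} in \code{fasta_dir}) into a target database;
#' when \code{with_decoys} every sequence is reversed and its accession
#' prefixed \code{DECOY_}, giving one decoy per target record.
#'
#' @param taxids taxids whose proteomes enter the database.
#' @param fasta_dir directory holding \code{<taxid>.faa} files.
#' @param out_prefix output path prefix; writes \code{<prefix>.faa} and,
#'   with decoys, \code{<prefix>_decoy.faa}.
#' @param with_decoys write the reversed-decoy companion (default TRUE).
#' @return invisibly, the path(s) written.
#' @export
write_subdatabase <- function(taxids, fasta_dir, out_prefix,
                              with_decoys = TRUE) {
  if (length(taxids) == 0L) {
    warning("empty sub-database specification; writing empty FASTA")
    seqs <- Biostrings::AAStringSet()
  } else {
    files <- file.path(fasta_dir, paste0(taxids, ".faa"))
    missing <- !file.exists(files)
    if (any(missing))
      stop("missing source FASTA for taxid(s): ",
           paste(taxids[missing], collapse = ", "))
    parts <- lapply(seq_along(files), function(i) {
      s <- Biostrings::readAAStringSet(files[i])
      names(s) <- paste0(sub(" .*", "", names(s)), " taxid=", taxids[i])
      s
    })
    seqs <- do.call(c, parts)
  }
  target_path <- paste0(out_prefix, ".faa")
  Biostrings::writeXStringSet(seqs, target_path)
  paths <- target_path
  if (with_decoys) {
    dec <- Biostrings::reverse(seqs)
    if (length(dec)) names(dec) <- paste0("DECOY_", names(seqs))
    decoy_path <- paste0(out_prefix, "_decoy.faa")
    Biostrings::writeXStringSet(dec, decoy_path)
    paths <- c(paths, decoy_path)
  }
  invisible(paths)
}

#' Export a sub-database specification as JSON
#'
#' @param partition output of \code{\link{partition_taxa}}.
#' @param representatives optional named list: species taxid ->
#'   representative data.frame from \code{\link{select_representatives}}.
#' @param path output JSON path.
#' @export
write_subdatabase_spec <- function(partition, representatives = NULL, path) {
  spec <- list(bins = lapply(partition, as.integer))
  if (!is.null(representatives)) spec$representatives <- representatives
  jsonlite::write_json(spec, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
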