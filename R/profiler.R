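#' Map distinct peptides to their taxon sets
#'
#' Collapses duplicate (I/L-canonical) peptides across the accepted target
#' PSMs and unions the taxids of every accession carrying each peptide.
#' Peptides whose accessions all fail to map are reported as orphans and
#' excluded from downstream profiles.
#'
#' @param psms accepted PSM data.frame (decoys are dropped here).
#' @param map accession->taxid map (\code{\link{load_accession_map}}).
#' @param tree \code{taxonomy_tree} (taxids are checked against it).
#' @return object of class \code{peptide_taxa}: a named list peptide ->
#'   integer taxid set, with attribute \code{orphans}.
#' @export
build_peptide_taxa <- function(psms, map, tree) {
  psms <- psms[!psms$is_decoy, , drop = FALSE]
  if (nrow(psms) == 0L) {
    out <- list()
    attr(out, "orphans") <- character(0)
    class(out) <- "peptide_taxa"
    return(out)
  }
  pep_acc <- split(unlist(psms$accessions,  use.names = FALSE),
                   rep(psms$peptide, lengths(psms$accessions)))
  out <- vector("list", length(pep_acc))
  names(out) <- names(pep_acc)
  orphans <- character(0)
  for (p in names(pep_acc)) {
    r <- resolve_accessions(unique(pep_acc[[p]]), map)
    tx <- r$taxids[r$taxids %in% tree$taxid]
    if (length(tx) == 0L) {
      orphans <- c(orphans, p)
    } else {
      out[[p]] <- tx
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "orphans") <- orphans
  class(out) <- "peptide_taxa"
  out
}

#' Map decoy peptides to taxa through their source proteins
#'
#' Decoy PSM accessions carry the \code{DECOY_} prefix of the protein whose
#' reversed sequence produced them; stripping the prefix recovers the
#' source protein, so decoy peptides inherit its taxonomy. Used for the
#' decoy side of the genus-level FDR estimate.
#'
#' @param psms PSM data.frame; only decoy rows are used.
#' @param map accession->taxid map.
#' @param tree \code{taxonomy_tree}.
#' @return a \code{peptide_taxa} object for the decoy peptides.
#' @export
build_decoy_peptide_taxa <- function(psms, map, tree) {
  dec <- psms[psms$is_decoy, , drop = FALSE]
  dec$accessions <- lapply(dec$accessions, function(a) sub("^DECOY_", "", a))
  dec$is_decoy <- rep(FALSE, nrow(dec))  # reuse the target-side machinery
  build_peptide_taxa(dec, map, tree)
}

#' Taxon a peptide is specific to at a rank
#'
#' A peptide is specific (unique) at a rank when every taxid in its set
#' projects to the same non-missing taxon at that rank.
#'
#' @param peptide one canonical peptide present in \code{ptx}.
#' @param rank canonical rank.
#' @param ptx a \code{peptide_taxa} object.
#' @param tree \code{taxonomy_tree}.
#' @return the taxid the peptide is specific to, or \code{NA}.
#' @export
is_specific <- function(peptide, rank, ptx, tree) {
  tx <- ptx[[peptide]]
  if (is.null(tx)) stop("peptide not in peptide_taxa: ", peptide)
  proj <- unique(project_to_rank(tree, tx, rank))
  if (length(proj) == 1L && !is.na(proj)) proj else NA_integer_
}

#' Collate taxon-to-spectrum matches up the canonical ranks
#'
#' For each taxon at each canonical rank, tallies: \code{tsm_count} (accepted
#' target PSMs whose peptide maps to at least one taxid projecting there —
#' each PSM counted once per taxon), \code{peptide_count} (distinct peptides,
#' analogously), and the corresponding specific counters restricted to
#' peptides specific at that rank.
#'
#' @param psms accepted PSM data.frame (decoys excluded internally).
#' @param ptx \code{peptide_taxa} from \code{\link{build_peptide_taxa}}.
#' @param tree \code{taxonomy_tree}.
#' @return a long data.frame of class \code{taxon_profile}: one row per
#'   (taxid, rank) with columns \code{taxid, rank, name, tsm_count,
#'   peptide_count, specific_peptide_count, specific_tsm_count}.
#' @export
collate_profile <- function(psms, ptx, tree) {
  psms <- psms[!psms$is_decoy, , drop = FALSE]
  psms <- psms[psms$peptide %in% names(ptx), , drop = FALSE]
  spec_per_pep <- table(psms$peptide)   # TSMs carried by each peptide

  rows <- list()
  for (rank in CANONICAL_RANKS) {
    # one projection per tree node, then constant-time lookups per peptide
    projv <- stats::setNames(project_to_rank(tree, tree$taxid, rank),
                             tree$taxid)
    acc <- new.env(parent = emptyenv())
    bump <- function(tab, key, by) {
      k <- as.character(key)
      cur <- if (is.null(tab[[k]])) c(0, 0, 0, 0) else tab[[k]]
      tab[[k]] <- cur + by
    }
    for (p in names(ptx)) {
      n_tsm <- if (p %in% names(spec_per_pep))
        as.integer(spec_per_pep[[p]]) else 0L
      if (n_tsm == 0L) next
      proj <- unique(unname(projv[as.character(ptx[[p]])]))
      proj <- proj[!is.na(proj)]
      if (length(proj) == 0L) next
      specific_to <- if (length(proj) == 1L) proj else NA_integer_
      for (t in proj) {
        sp <- !is.na(specific_to) && t == specific_to
        bump(acc, t, c(n_tsm, 1L, if (sp) 1L else 0L, if (sp) n_tsm else 0L))
      }
    }
    for (t in ls(acc)) {
      v <- acc[[t]]
      rows[[length(rows) + 1L]] <-
        data.frame(taxid = as.integer(t), rank = rank,
                   tsm_count = as.integer(v[1]),
                   peptide_count = as.integer(v[2]),
                   specific_peptide_count = as.integer(v[3]),
                   specific_tsm_count = as.integer(v[4]),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    prof <- data.frame(taxid = integer(0), rank = character(0),
                       name = character(0), tsm_count = integer(0),
                       peptide_count = integer(0),
                       specific_peptide_count = integer(0),
                       specific_tsm_count = integer(0),
                       stringsAsFactors = FALSE)
  } else {
    prof <- do.call(rbind, rows)
    prof$name <- tax_name(tree, prof$taxid)
    prof <- prof[, c("taxid", "rank", "name", "tsm_count", "peptide_count",
                     "specific_peptide_count", "specific_tsm_count")]
    prof <- prof[order(match(prof$rank, CANONICAL_RANKS), prof$taxid), ]
    rownames(prof) <- NULL
  }
  class(prof) <- c("taxon_profile", "data.frame")
  prof
}

#' Relative biomass shares at a rank
#'
#' Shares are specific TSMs of each taxon divided by the total specific TSMs
#' at the reporting rank (genus by default); taxa with zero specific TSMs
#' are omitted, and shares sum to one.
#'
#' @param profile a \code{taxon_profile}.
#' @param rank canonical reporting rank.
#' @return data.frame \code{taxid, name, specific_tsm_count, share}, sorted
#'   by decreasing share.
#' @export
biomass_shares <- function(profile, rank = "genus") {
  rank <- match.arg(rank, CANONICAL_RANKS)
  rows <- profile[profile$rank == rank & profile$specific_tsm_count > 0, ,
                  drop = FALSE]
  total <- sum(rows$specific_tsm_count)
  if (total == 0)
    stop("no specific TSMs at rank ", rank, "; biomass shares undefined")
  out <- data.frame(taxid = rows$taxid, name = rows$name,
                    specific_tsm_count = rows$specific_tsm_count,
                    share = rows$specific_tsm_count / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share, out$taxid), ]
  rownames(out) <- NULL
  out
}

#' Write a taxon profile as TSV
#' @param profile a \code{taxon_profile}.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
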