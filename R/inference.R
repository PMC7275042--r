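#' PSM-level FDR filtering by target-decoy competition
#'
#' Orders PSMs by expectation value (ascending) and keeps the largest
#' prefix for which cumulative decoys / cumulative targets does not exceed
#' \code{fdr}; target PSMs in that prefix are returned for inference.
#'
#' @param psms PSM data.frame with targets and decoys.
#' @param fdr maximum PSM-level FDR (default 0.01).
#' @return target PSMs passing the threshold.
#' @export
filter_psm_fdr <- function(psms, fdr = 0.01) {
  if (nrow(psms) == 0L) return(psms)
  ord <- order(psms$expectation, psms$is_decoy)  # target wins exact ties
  d <- cumsum(psms$is_decoy[ord])
  t <- cumsum(!psms$is_decoy[ord])
  ok <- which(t > 0 & d / t <= fdr)
  if (length(ok) == 0L) return(psms[0, , drop = FALSE])
  keep <- ord[seq_len(max(ok))]
  out <- psms[sort(keep), , drop = FALSE]
  out[!out$is_decoy, , drop = FALSE]
}

# union-find over protein indices
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Group proteins sharing peptides, with parsimony collapse
#'
#' Proteins are grouped when they share at least one peptide (connected
#' components of the protein-peptide bipartite graph). Within a component,
#' proteins whose peptide sets are subsets of another member's are subsumed
#' under the maximal protein; the retained (non-subsumed) members realize
#' the parsimonious explanation of the component's peptides. The anchor is
#' the member covering the most distinct peptides (ties broken
#' lexicographically).
#'
#' @param pep2acc named list: peptide -> character vector of protein
#'   accessions carrying it.
#' @return data.frame of class \code{protein_groups}: one row per group
#'   with \code{group_id, anchor, n_peptides} and list columns
#'   \code{members} (all component proteins), \code{retained}
#'   (post-collapse), \code{peptides}.
#' @export
group_proteins <- function(pep2acc) {
  stopifnot(length(pep2acc) > 0L)
  prot <- sort(unique(unlist(pep2acc, use.names = FALSE)))
  pidx <- stats::setNames(seq_along(prot), prot)
  # peptide sets per protein
  acc2pep <- split(rep(names(pep2acc), lengths(pep2acc)),
                   unlist(pep2acc, use.names = FALSE))
  acc2pep <- lapply(acc2pep, unique)[prot]

  parent <- seq_along(prot)
  for (accs in pep2acc) {
    i0 <- uf_find(parent, pidx[[accs[1]]])
    for (a in accs[-1]) {
      j <- uf_find(parent, pidx[[a]])
      if (j != i0) parent[j] <- i0
    }
  }
  comp <- vapply(seq_along(prot), function(i) uf_find(parent, i), integer(1))

  groups <- lapply(split(seq_along(prot), comp), function(members) {
    peps <- acc2pep[members]
    nms <- prot[members]
    # subset collapse: drop proteins whose peptide set is contained in
    # another member's (proper subset, or identical set of a
    # lexicographically earlier protein)
    keep <- rep(TRUE, length(members))
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (i == j || !keep[i]) next
        sub_ij <- all(peps[[i]] %in% peps[[j]])
        if (sub_ij && (length(peps[[i]]) < length(peps[[j]]) ||
                       (length(peps[[i]]) == length(peps[[j]]) &&
                        nms[j] < nms[i])))
          keep[i] <- FALSE
      }
    }
    all_pep <- sort(unique(unlist(peps, use.names = FALSE)))
    n_pep_per <- lengths(peps)
    anchor <- nms[order(-n_pep_per, nms)][1]
    list(members = sort(nms), retained = sort(nms[keep]),
         peptides = all_pep, anchor = anchor,
         n_peptides = length(all_pep))
  })
  # deterministic ordering by anchor accession
  groups <- groups[order(vapply(groups, `[[`, character(1), "anchor"))]
  out <- data.frame(group_id = seq_along(groups),
                    anchor = vapply(groups, `[[`, character(1), "anchor"),
                    n_peptides = vapply(groups, `[[`, integer(1),
                                        "n_peptides"),
                    stringsAsFactors = FALSE)
  out$members <- lapply(groups, `[[`, "members")
  out$retained <- lapply(groups, `[[`, "retained")
  out$peptides <- lapply(groups, `[[`, "peptides")
  rownames(out) <- NULL
  class(out) <- c("protein_groups", "data.frame")
  out
}

#' Assign spectral counts to protein groups (razor rule)
#'
#' Each accepted PSM contributes exactly one count. PSMs whose accessions
#' fall in a single group go there; PSMs spanning several groups are
#' assigned to the group with the largest provisional (unambiguous) count,
#' ties broken by smallest group id. Total assigned counts equal the number
#' of accepted PSMs.
#'
#' @param groups a \code{protein_groups} data.frame.
#' @param psms accepted target PSM data.frame.
#' @return \code{groups} with a \code{spectral_count} column.
#' @export
assign_spectral_counts <- function(groups, psms) {
  acc2grp <- stats::setNames(
    rep(groups$group_id, lengths(groups$members)),
    unlist(groups$members, use.names = FALSE))
  psm_groups <- lapply(psms$accessions, function(a) {
    g <- unique(unname(acc2grp[a]))
    if (anyNA(g))
      stop("PSM accession(s) in no group: ",
           paste(a[is.na(acc2grp[a])], collapse = ", "))
    g
  })
  counts <- integer(nrow(groups))
  multi <- lengths(psm_groups) > 1L
  for (g in unlist(psm_groups[!multi]))
    counts[g] <- counts[g] + 1L          # pass 1: unambiguous PSMs
  for (gs in psm_groups[multi]) {        # pass 2: razor assignment
    gs <- sort(gs)
    win <- gs[which.max(counts[gs])]     # ties -> smallest group_id
    counts[win] <- counts[win] + 1L
  }
  groups$spectral_count <- counts
  groups
}

#' Label protein groups with their sub-database bin
#'
#' The bin of a group is the bin of its members; groups whose members span
#' several bins are flagged and resolved to the anchor's bin.
#'
#' @param groups a \code{protein_groups} data.frame.
#' @param accession_bins named character vector: accession ->
#'   \code{"host"}, \code{"food"} or \code{"microbiome"}.
#' @return \code{groups} with \code{bin} and \code{mixed_bin} columns.
#' @export
bin_groups <- function(groups, accession_bins) {
  bins <- lapply(groups$members, function(m) {
    b <- accession_bins[m]
    if (anyNA(b))
      stop("accession(s) traceable to no sub-database: ",
           paste(m[is.na(b)], collapse = ", "))
    unique(unname(b))
  })
  groups$mixed_bin <- lengths(bins) > 1L
  groups$bin <- ifelse(groups$mixed_bin,
                       unname(accession_bins[groups$anchor]),
                       vapply(bins, `[`, character(1), 1))
  groups
}

#' Write quantified protein groups as TSV
#' @param groups quantified, binned \code{protein_groups}.
#' @param path output path.
#' @export
write_protein_groups <- function(groups, path) {
  flat <- data.frame(group_id = groups$group_id, anchor = groups$anchor,
                     members = vapply(groups$members, paste,
                                      character(1), collapse = ";"),
                     n_peptides = groups$n_peptides,
                     spectral_count = groups$spectral_count,
                     bin = groups$bin, stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
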