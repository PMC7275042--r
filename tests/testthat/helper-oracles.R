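# Independent brute-force oracles used to cross-check the implementation.
# These operate directly on raw tables and never call the code paths they
# verify.

# ancestor-or-self at a rank by explicit parent-chain walk on the raw table
oracle_project <- function(tax_df, taxid, rank) {
  cur <- taxid
  repeat {
    row <- tax_df[tax_df$taxid == cur, ]
    if (row$rank == rank) return(row$taxid)
    if (row$parent_taxid == cur || row$parent_taxid == 0) return(NA_integer_)
    cur <- row$parent_taxid
  }
}

# full recount of all four profile counters, enumerating every
# (peptide, PSM, rank) triple
oracle_profile <- function(target_psms, pep2tax, tax_df, ranks) {
  out <- list()
  for (r in ranks) {
    proj <- lapply(pep2tax, function(tx)
      unique(stats::na.omit(vapply(tx, oracle_project, integer(1),
                                   tax_df = tax_df, rank = r))))
    taxa <- sort(unique(unlist(proj)))
    for (t in taxa) {
      peps <- names(proj)[vapply(proj, function(p) t %in% p, logical(1))]
      spec_peps <- names(proj)[vapply(proj, function(p)
        length(p) == 1L && p == t, logical(1))]
      n_tsm <- sum(target_psms$peptide %in% peps)
      n_stsm <- sum(target_psms$peptide %in% spec_peps)
      out[[paste(t, r)]] <- data.frame(
        taxid = t, rank = r, tsm_count = n_tsm,
        peptide_count = sum(peps %in% target_psms$peptide),
        specific_peptide_count = sum(spec_peps %in% target_psms$peptide),
        specific_tsm_count = n_stsm, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$tsm_count > 0, ]
  rownames(res) <- NULL
  res[order(match(res$rank, ranks), res$taxid), ]
}

# literal step-by-step simulation of the greedy representative rule
oracle_greedy <- function(coverage, max_taxa = 10L, min_added = 2L) {
  ids <- as.integer(names(coverage))
  sizes <- vapply(coverage, function(x) length(unique(x)), integer(1))
  order_idx <- order(-sizes, ids)
  chosen <- integer(0)
  covered <- character(0)
  for (i in order_idx) {
    if (length(chosen) == max_taxa) break
    novel <- setdiff(unique(coverage[[i]]), covered)
    if (length(novel) >= min_added) {
      chosen <- c(chosen, ids[i])
      covered <- union(covered, coverage[[i]])
    }
  }
  chosen
}

# exhaustive search for minimal protein sets explaining all peptides;
# returns all minimum-cardinality covers
oracle_min_covers <- function(pep2acc) {
  prots <- sort(unique(unlist(pep2acc)))
  peps <- names(pep2acc)
  best <- NULL; best_size <- Inf
  for (k in seq_along(prots)) {
    if (k > best_size) break
    combs <- utils::combn(prots, k, simplify = FALSE)
    for (s in combs) {
      if (all(vapply(pep2acc, function(a) any(a %in% s), logical(1)))) {
        if (k < best_size) { best <- list(); best_size <- k }
        best[[length(best) + 1L]] <- s
      }
    }
    if (!is.infinite(best_size)) break
  }
  best
}

# exhaustive ancestor-path enumeration for slim mapping: the first slim
# term on each upward path, reduced to an antichain
oracle_slim <- function(term, slim, parents) {
  anc_of <- function(x) {        # all strict+self ancestors by BFS
    seen <- character(0); frontier <- x
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(parents[frontier], use.names = FALSE), seen)
    }
    seen
  }
  firsts <- character(0)
  walk <- function(node) {
    if (node %in% slim) { firsts <<- union(firsts, node); return(invisible()) }
    for (p in parents[[node]] %||% character(0)) walk(p)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  if (term %in% slim) return(term)
  for (p in parents[[term]]) walk(p)
  # antichain reduction: drop terms that are strict ancestors of others
  keep <- vapply(firsts, function(f)
    !any(vapply(setdiff(firsts, f), function(o) f %in% anc_of(o),
                logical(1))), logical(1))
  sort(firsts[keep])
}

# small fixed 12-node taxonomy used across tests
fixture_tree_df <- function() {
  data.frame(
    taxid = c(1L, 2L, 3L, 10L, 11L, 12L, 13L, 14L, 15L, 20L, 21L, 22L),
    parent_taxid = c(1L, 1L, 1L, 2L, 10L, 11L, 12L, 13L, 13L, 3L, 20L, 21L),
    rank = c("no_rank", "superkingdom", "superkingdom", "phylum", "class",
             "order", "genus", "species", "species", "phylum", "family",
             "species"),
    name = c("root", "Bacteria", "Eukaryota", "p1", "c1", "o1", "g1",
             "s1", "s2", "p2", "f2", "s3"),
    stringsAsFactors = FALSE)
}
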