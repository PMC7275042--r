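CANONICAL_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' Canonical taxonomic ranks, most to least inclusive
#' @return character vector of the seven canonical ranks.
#' @export
canonical_ranks <- function() CANONICAL_RANKS

#' Load a taxonomy table into an in-memory tree
#'
#' Reads a tab-separated nodes table (columns \code{taxid}, \code{parent_taxid},
#' \code{rank}, \code{name}) and builds a tree supporting ancestor queries.
#' Exactly one root is required, encoded as a node whose parent is itself or 0.
#' Non-canonical ranks (strain, subspecies, \code{no_rank}) are carried
#' transparently; they are projected through but never receive counts.
#'
#' @param path path to the TSV nodes table, or a \code{data.frame} with the
#'   same columns.
#' @return an object of class \code{taxonomy_tree}.
#' @export
load_taxonomy <- function(path) {
  nodes <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  req <- c("taxid", "parent_taxid", "rank", "name")
  miss <- setdiff(req, names(nodes))
  if (length(miss))
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  taxid <- as.integer(nodes$taxid)
  parent <- as.integer(nodes$parent_taxid)
  if (anyDuplicated(taxid))
    stop("duplicate taxid(s): ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  is_root <- parent == taxid | parent == 0L
  if (sum(is_root) != 1L)
    stop("taxonomy must have exactly one root, found ", sum(is_root))
  orphan <- !is_root & !(parent %in% taxid)
  if (any(orphan))
    stop("orphan parent(s) for taxid(s): ",
         paste(taxid[orphan], collapse = ", "))

  idx <- match(parent, taxid)          # parent row index; NA only at root
  idx[is_root] <- NA_integer_

  # cycle check: walk every node to the root, bounded by node count
  n <- length(taxid)
  for (start in seq_len(n)) {
    i <- start
    steps <- 0L
    while (!is.na(i)) {
      i <- idx[i]
      steps <- steps + 1L
      if (steps > n)
        stop("cycle detected in taxonomy at taxid ", taxid[start])
    }
  }

  tree <- list(taxid = taxid, parent_idx = idx,
               rank = as.character(nodes$rank),
               name = as.character(nodes$name),
               root = taxid[is_root],
               lookup = stats::setNames(seq_len(n), taxid))
  class(tree) <- "taxonomy_tree"
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree with", length(x$taxid), "nodes, root taxid", x$root, "\n")
  tab <- table(factor(x$rank, levels = c(CANONICAL_RANKS, "no_rank")))
  cat("  ranks:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

tax_index <- function(tree, taxid) {
  i <- tree$lookup[as.character(taxid)]
  if (anyNA(i))
    stop("unknown taxid(s): ", paste(taxid[is.na(i)], collapse = ", "))
  unname(i)
}

#' Project a taxon to a canonical rank
#'
#' Walks the parent chain from \code{taxid} and returns the unique
#' ancestor-or-self at the requested canonical rank, or \code{NA} when the
#' lineage skips that rank. Vectorized over \code{taxid}.
#'
#' @param tree a \code{taxonomy_tree}.
#' @param taxid integer taxid(s), all present in the tree.
#' @param rank one of the canonical ranks.
#' @return integer vector of taxids (NA where the rank is absent).
#' @export
project_to_rank <- function(tree, taxid, rank) {
  rank <- match.arg(rank, CANONICAL_RANKS)
  i <- tax_index(tree, taxid)
  out <- rep(NA_integer_, length(i))
  for (k in seq_along(i)) {
    j <- i[k]
    while (!is.na(j)) {
      if (tree$rank[j] == rank) { out[k] <- tree$taxid[j]; break }
      j <- tree$parent_idx[j]
    }
  }
  out
}

#' Full canonical lineage of a taxon
#'
#' @param tree a \code{taxonomy_tree}.
#' @param taxid a single taxid.
#' @return named integer vector over the canonical ranks (NA where absent).
#' @export
lineage <- function(tree, taxid) {
  stats::setNames(
    vapply(CANONICAL_RANKS, function(r) project_to_rank(tree, taxid, r),
           integer(1)),
    CANONICAL_RANKS)
}

tax_name <- function(tree, taxid) tree$name[tax_index(tree, taxid)]

#' Test ancestry within the tree
#'
#' @param tree a \code{taxonomy_tree}.
#' @param ancestor candidate ancestor taxid (single).
#' @param taxid taxid(s) to test; a taxon is its own ancestor.
#' @return logical vector.
#' @export
is_ancestor <- function(tree, ancestor, taxid) {
  anc_i <- tax_index(tree, ancestor)
  vapply(tax_index(tree, taxid), function(j) {
    while (!is.na(j)) {
      if (j == anc_i) return(TRUE)
      j <- tree$parent_idx[j]
    }
    FALSE
  }, logical(1))
}

#' Load an accession-to-taxid map
#'
#' TSV with header \code{accession<TAB>taxid} (an accession2taxid-compatible
#' subset). Every mapped taxid must exist in \code{tree} when one is supplied.
#'
#' @param path TSV path or data.frame.
#' @param tree optional \code{taxonomy_tree} for consistency checking.
#' @return named integer vector: accession -> taxid.
#' @export
load_accession_map <- function(path, tree = NULL) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("accession", "taxid") %in% names(tab)))
    stop("accession map needs columns: accession, taxid")
  map <- stats::setNames(as.integer(tab$taxid), as.character(tab$accession))
  if (!is.null(tree)) {
    bad <- !(map %in% tree$taxid)
    if (any(bad))
      stop("accession map references taxid(s) absent from the tree: ",
           paste(unique(map[bad]), collapse = ", "))
  }
  map
}

#' Resolve protein accessions to taxids
#'
#' @param accessions character vector of accessions.
#' @param map named integer vector from \code{\link{load_accession_map}}.
#' @return list with \code{taxids} (deduplicated integer set) and
#'   \code{unmapped} (accessions not present in the map; never silently
#'   dropped).
#' @export
resolve_accessions <- function(accessions, map) {
  hit <- accessions %in% names(map)
  list(taxids = sort(unique(unname(map[accessions[hit]]))),
       unmapped = accessions[!hit])
}
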