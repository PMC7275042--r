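#' Load a Gene Ontology DAG from an OBO 1.2 file
#'
#' Parses \code{[Term]} stanzas (id, name, namespace, alt_id, is_a,
#' relationship: part_of, is_obsolete). Obsolete terms are excluded;
#' alternative ids resolve to their primary record. \code{part_of} edges are
#' treated as parent edges by default, mirroring Map2Slim behaviour.
#'
#' @param path OBO file path.
#' @param use_part_of follow \code{part_of} relationships (default TRUE).
#' @return object of class \code{go_dag}: list with \code{parents} (term ->
#'   character vector), \code{name}, \code{namespace}, \code{alt} (alt_id ->
#'   primary id).
#' @export
load_obo <- function(path, use_part_of = TRUE) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  parents <- list(); nm <- character(0); ns <- character(0)
  alt <- character(0)
  for (s in seq_along(starts)) {
    chunk <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    field <- function(key) sub(paste0("^", key, ": *"), "",
                               grep(paste0("^", key, ":"), chunk,
                                    value = TRUE))
    if (any(grepl("^is_obsolete: *true", chunk))) next
    id <- field("id")[1]
    if (is.na(id)) next
    isa <- sub(" *!.*$", "", field("is_a"))
    par <- isa
    if (use_part_of) {
      rel <- field("relationship")
      po <- sub(" *!.*$", "", sub("^part_of +", "", rel[grepl("^part_of ",
                                                              rel)]))
      par <- c(par, po)
    }
    parents[[id]] <- unique(par)
    nm[id] <- if (length(field("name"))) field("name")[1] else id
    ns[id] <- if (length(field("namespace"))) field("namespace")[1] else NA
    for (a in field("alt_id")) alt[a] <- id
  }
  dag <- list(parents = parents, name = nm, namespace = ns, alt = alt)
  class(dag) <- "go_dag"
  # acyclicity check by depth-first traversal with a visitation stack
  state <- stats::setNames(integer(length(parents)), names(parents))
  visit <- function(id, stack) {
    if (id %in% stack) stop("cycle detected in GO DAG at ", id)
    if (!is.na(state[id]) && state[id] == 2L) return(invisible())
    state[id] <<- 2L
    for (p in dag$parents[[id]])
      if (p %in% names(parents)) visit(p, c(stack, id))
    invisible()
  }
  for (id in names(parents)) visit(id, character(0))
  dag
}

go_primary <- function(dag, term) {
  out <- term
  is_alt <- term %in% names(dag$alt)
  out[is_alt] <- unname(dag$alt[term[is_alt]])
  out
}

go_in_dag <- function(dag, term) go_primary(dag, term) %in%
  names(dag$parents)

go_ancestors <- function(dag, term) {
  # all ancestors including the term itself
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unlist(dag$parents[intersect(frontier, names(dag$parents))],
             use.names = FALSE),
      seen)
  }
  seen
}

#' Map a GO term to its minimal GOslim ancestors
#'
#' Returns the slim terms reachable from \code{term} through ancestor paths
#' such that no other returned slim term lies strictly between (the
#' Map2Slim rule); the result is an antichain. A term already in the slim
#' maps to itself.
#'
#' @param term a GO id (alt_ids are resolved).
#' @param slim character vector of slim GO ids.
#' @param dag a \code{go_dag}.
#' @return character vector of minimal slim ancestors (possibly empty).
#' @export
map_to_slim <- function(term, slim, dag) {
  term <- go_primary(dag, term)
  if (!term %in% names(dag$parents)) stop("GO term not in DAG: ", term)
  slim <- go_primary(dag, slim)
  anc <- go_ancestors(dag, term)
  hits <- intersect(anc, slim)
  if (length(hits) <= 1L) return(hits)
  # drop any slim hit that is a strict ancestor of another slim hit
  minimal <- hits[vapply(hits, function(h) {
    others <- setdiff(hits, h)
    !any(vapply(others, function(o) h %in% go_ancestors(dag, o) && o != h,
                logical(1)))
  }, logical(1))]
  sort(minimal)
}

#' Load protein-to-GO annotations
#'
#' TSV with header \code{accession<TAB>go_id}, one row per pair.
#'
#' @param path TSV path or data.frame.
#' @return named list: accession -> character vector of GO ids.
#' @export
load_go_annotations <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("accession", "go_id") %in% names(tab)))
    stop("annotation table needs columns: accession, go_id")
  lapply(split(tab$go_id, tab$accession), unique)
}

#' GOslim abundance profile of the microbial protein groups
#'
#' Each microbiome-bin group contributes its full spectral count to every
#' minimal slim ancestor of each of its GO terms (counts are duplicated
#' across slim terms, never split). Group-level GO terms come from the
#' anchor accession, falling back to the union over members when the anchor
#' is unannotated. Annotations absent from the DAG are skipped and
#' reported; groups with no usable annotation are tallied separately.
#'
#' @param groups quantified, binned \code{protein_groups}.
#' @param annotations accession -> GO ids
#'   (\code{\link{load_go_annotations}}).
#' @param slim character vector of slim GO ids.
#' @param dag a \code{go_dag}.
#' @param bin which bin to profile (default \code{"microbiome"}).
#' @return object of class \code{goslim_profile}: data.frame
#'   \code{slim_id, name, namespace, spectral_count}, with attributes
#'   \code{unannotated_groups} and \code{skipped_annotations}.
#' @export
goslim_abundance <- function(groups, annotations, slim, dag,
                             bin = "microbiome") {
  sel <- groups[groups$bin == bin, , drop = FALSE]
  totals <- stats::setNames(numeric(length(slim)), go_primary(dag, slim))
  unannotated <- character(0); skipped <- character(0)
  for (i in seq_len(nrow(sel))) {
    gos <- annotations[[sel$anchor[i]]]
    if (is.null(gos))
      gos <- unique(unlist(annotations[sel$members[[i]]],
                           use.names = FALSE))
    if (is.null(gos) || length(gos) == 0L) {
      unannotated <- c(unannotated, sel$anchor[i])
      next
    }
    in_dag <- go_in_dag(dag, gos)
    if (any(!in_dag)) {
      skipped <- c(skipped, gos[!in_dag])
      warning("skipping GO id(s) absent from DAG: ",
              paste(gos[!in_dag], collapse = ", "), call. = FALSE)
    }
    slims <- unique(unlist(lapply(gos[in_dag], map_to_slim, slim = slim,
                                  dag = dag), use.names = FALSE))
    for (s in slims) totals[s] <- totals[s] + sel$spectral_count[i]
  }
  out <- data.frame(slim_id = names(totals),
                    name = unname(dag$name[names(totals)]),
                    namespace = unname(dag$namespace[names(totals)]),
                    spectral_count = as.integer(unname(totals)),
                    stringsAsFactors = FALSE)
  out <- out[out$spectral_count > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unannotated_groups") <- unannotated
  attr(out, "skipped_annotations") <- skipped
  class(out) <- c("goslim_profile", "data.frame")
  out
}
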