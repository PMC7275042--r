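#' Call genera from peptide evidence
#'
#' A genus is called when at least \code{min_specific} distinct
#' genus-specific peptides support it. The target and decoy peptide pools
#' are evaluated independently; decoy peptides inherit the taxonomy of the
#' proteins they were reversed from, so decoy calls estimate the rate of
#' chance specificity.
#'
#' @param target_ptx \code{peptide_taxa} built from target PSMs.
#' @param decoy_ptx \code{peptide_taxa} built from decoy PSMs (mapped via
#'   their pre-reversal source proteins); may be empty.
#' @param tree \code{taxonomy_tree}.
#' @param min_specific minimum distinct genus-specific peptides (default 3).
#' @return data.frame of class \code{genus_calls}: \code{taxid, name,
#'   n_specific_peptides, source} (\code{target} / \code{decoy}).
#' @export
call_genera <- function(target_ptx, decoy_ptx, tree, min_specific = 3L) {
  call_pool <- function(ptx, source) {
    if (length(ptx) == 0L)
      return(data.frame(taxid = integer(0), name = character(0),
                        n_specific_peptides = integer(0),
                        source = character(0), stringsAsFactors = FALSE))
    projv <- stats::setNames(project_to_rank(tree, tree$taxid, "genus"),
                             tree$taxid)
    gen <- vapply(ptx, function(tx) {
      g <- unique(unname(projv[as.character(tx)]))
      if (length(g) == 1L && !is.na(g)) g else NA_integer_
    }, integer(1))
    gen <- gen[!is.na(gen)]
    if (length(gen) == 0L)
      return(data.frame(taxid = integer(0), name = character(0),
                        n_specific_peptides = integer(0),
                        source = character(0), stringsAsFactors = FALSE))
    counts <- table(gen)                 # distinct peptides per genus
    called <- counts[counts >= min_specific]
    data.frame(taxid = as.integer(names(called)),
               name = tax_name(tree, as.integer(names(called))),
               n_specific_peptides = as.integer(called),
               source = rep(source, length(called)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(call_pool(target_ptx, "target"), call_pool(decoy_ptx, "decoy"))
  out <- out[order(out$source, out$taxid), ]
  rownames(out) <- NULL
  class(out) <- c("genus_calls", "data.frame")
  out
}

#' Estimate the genus-level taxonomic FDR
#'
#' FDR = number of decoy genus calls / number of target genus calls.
#'
#' @param calls a \code{genus_calls} data.frame.
#' @return list \code{fdr, n_target, n_decoy}.
#' @export
estimate_taxonomic_fdr <- function(calls) {
  n_target <- sum(calls$source == "target")
  n_decoy <- sum(calls$source == "decoy")
  if (n_target == 0L)
    stop("no target genus calls; FDR undefined")
  list(fdr = n_decoy / n_target, n_target = n_target, n_decoy = n_decoy)
}

#' Write a genus-call report
#'
#' TSV of calls followed by a one-line summary
#' \code{fdr=<value> target=<n> decoy=<n>}.
#'
#' @param calls a \code{genus_calls} data.frame.
#' @param path output path.
#' @export
write_genus_report <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f <- estimate_taxonomic_fdr(calls)
  cat(sprintf("# fdr=%g target=%d decoy=%d\n", f$fdr, f$n_target, f$n_decoy),
      file = path, append = TRUE)
  invisible(path)
}
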