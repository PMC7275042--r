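AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Canonicalize a peptide string
#'
#' Uppercases, strips flanking residues written as \code{X.PEPTIDE.Y}, removes
#' modification annotations in brackets/parentheses, and equates leucine with
#' isoleucine (I -> L) so that peptides indistinguishable by mass spectrometry
#' collapse to one key.
#'
#' @param peptide character vector of peptide strings.
#' @return canonical peptide strings.
#' @export
canonicalize_peptide <- function(peptide) {
  p <- toupper(peptide)
  p <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", p)        # drop modification tags
  has_flank <- grepl("^.?\\..+\\..?$", p)
  p[has_flank] <- sub("^.?\\.", "", sub("\\..?$", "", p[has_flank]))
  chartr("I", "L", p)
}

#' Read a PSM table
#'
#' Tab-separated, header
#' \code{spectrum_id peptide ion_score expectation accessions is_decoy};
#' accessions are \code{;}-separated, decoy accessions prefixed
#' \code{DECOY_}. Malformed rows are collected and reported together with
#' their line numbers.
#'
#' @param path TSV path.
#' @return data.frame with one row per PSM; \code{accessions} is a list
#'   column; peptides are canonicalized (see
#'   \code{\link{canonicalize_peptide}}).
#' @export
read_psm_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  req <- c("spectrum_id", "peptide", "ion_score", "expectation",
           "accessions", "is_decoy")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "))
  errs <- character(0)
  line <- seq_len(nrow(tab)) + 1L        # +1 for the header line
  pep <- toupper(tab$peptide)
  bad_pep <- pep == "" | !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"),
                                gsub("\\[[^]]*\\]|\\([^)]*\\)|\\.", "", pep))
  if (any(bad_pep))
    errs <- c(errs, paste0("line ", line[bad_pep],
                           ": empty or non-amino-acid peptide"))
  score <- suppressWarnings(as.numeric(tab$ion_score))
  expe <- suppressWarnings(as.numeric(tab$expectation))
  if (any(is.na(score)))
    errs <- c(errs, paste0("line ", line[is.na(score)],
                           ": non-numeric ion_score"))
  if (any(is.na(expe) | expe <= 0, na.rm = FALSE))
    errs <- c(errs, paste0("line ", line[is.na(expe) | expe <= 0],
                           ": expectation must be a positive number"))
  acc <- strsplit(tab$accessions, ";", fixed = TRUE)
  if (any(lengths(acc) == 0L | tab$accessions == ""))
    errs <- c(errs, paste0("line ", line[lengths(acc) == 0L |
                                           tab$accessions == ""],
                           ": no accessions"))
  if (length(errs))
    stop("malformed PSM rows:\n  ", paste(errs, collapse = "\n  "))
  psms <- data.frame(spectrum_id = tab$spectrum_id,
                     peptide = canonicalize_peptide(tab$peptide),
                     ion_score = score,
                     expectation = expe,
                     is_decoy = tolower(tab$is_decoy) %in%
                       c("true", "t", "1", "yes"),
                     stringsAsFactors = FALSE)
  psms$accessions <- acc
  # a PSM is decoy iff all its accessions are decoy accessions
  all_decoy <- vapply(acc, function(a) all(startsWith(a, "DECOY_")),
                      logical(1))
  if (any(psms$is_decoy != all_decoy))
    stop("decoy flag inconsistent with accessions at line(s): ",
         paste(line[psms$is_decoy != all_decoy], collapse = ", "))
  psms
}

#' Validate PSMs on the expectation value
#'
#' Keeps matches with expectation strictly below the cutoff (0.05 by
#' default); input order is preserved.
#'
#' @param psms PSM data.frame.
#' @param expectation_cutoff positive cutoff; strict inequality.
#' @return the surviving rows.
#' @export
validate_psms <- function(psms, expectation_cutoff = 0.05) {
  stopifnot(expectation_cutoff > 0)
  psms[psms$expectation < expectation_cutoff, , drop = FALSE]
}

#' Per-spectrum multiple-PSM acceptance
#'
#' Within each spectrum the top-scoring PSM is always kept; additional PSMs
#' are kept when their ion score is strictly higher than \code{fraction}
#' times the top score. Ties at the top are all kept.
#'
#' @param psms expectation-validated PSM data.frame.
#' @param fraction fraction of the top ion score (default 0.98).
#' @return data.frame of accepted PSMs (the validated spectrum set).
#' @export
select_spectrum_psms <- function(psms, fraction = 0.98) {
  if (nrow(psms) == 0L) return(psms)
  top <- stats::ave(psms$ion_score, psms$spectrum_id, FUN = max)
  keep <- psms$ion_score == top | psms$ion_score > fraction * top
  psms[keep, , drop = FALSE]
}
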