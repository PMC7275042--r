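#' Total-sum scaling of a count matrix
#'
#' Divides each sample column by its total so that columns sum to one
#' (relative abundances).
#'
#' @param counts numeric matrix, features x samples, non-negative.
#' @return matrix of the same shape with unit column sums.
#' @export
total_sum_scale <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot, "/")
}

#' Average technical replicates into biological replicates
#'
#' @param mat features x samples matrix.
#' @param meta data.frame with columns \code{sample, tissue, bio_rep}
#'   (\code{tech_rep} optional); \code{meta$sample} must match
#'   \code{colnames(mat)}.
#' @return list \code{mat} (features x biological replicates) and
#'   \code{groups} (tissue label per column).
#' @export
collapse_tech_reps <- function(mat, meta) {
  stopifnot(all(colnames(mat) %in% meta$sample))
  meta <- meta[match(colnames(mat), meta$sample), ]
  key <- paste(meta$tissue, meta$bio_rep, sep = "_")
  agg <- sapply(unique(key), function(k)
    rowMeans(mat[, key == k, drop = FALSE]))
  rownames(agg) <- rownames(mat)
  list(mat = agg,
       groups = meta$tissue[match(unique(key), key)])
}

#' Per-feature exact Wilcoxon tests with Benjamini-Hochberg correction
#'
#' Two-sided exact rank-sum test per feature between the two groups
#' (suitable for the small replicate numbers typical of tissue
#' comparisons), BH adjustment across features, fold change as the ratio of
#' group medians (larger over smaller, direction recorded). A feature is
#' significant when fold change exceeds \code{fc_threshold} and adjusted p
#' is below \code{alpha}. Features constant across all samples get p = 1
#' and are flagged.
#'
#' @param mat scaled features x samples matrix.
#' @param groups group label per column (exactly two levels, each with at
#'   least two samples).
#' @param fc_threshold fold-change threshold (default 1.5, exclusive).
#' @param alpha significance level on adjusted p (default 0.05, exclusive).
#' @param pseudo_count added to both medians before the ratio (default 0;
#'   zero medians then yield infinite fold change, flagged).
#' @return data.frame: \code{feature, median_<g1>, median_<g2>,
#'   fold_change, direction, p_value, adj_p, significant, constant}.
#' @export
wilcoxon_bh <- function(mat, groups, fc_threshold = 1.5, alpha = 0.05,
                        pseudo_count = 0) {
  groups <- as.character(groups)
  lev <- unique(groups)
  stopifnot(length(lev) == 2L, all(table(groups) >= 2L))
  a <- mat[, groups == lev[1], drop = FALSE]
  b <- mat[, groups == lev[2], drop = FALSE]
  n <- nrow(mat)
  p <- numeric(n); constant <- logical(n)
  med_a <- apply(a, 1, stats::median)
  med_b <- apply(b, 1, stats::median)
  for (i in seq_len(n)) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(c(x, y)) == 0) {      # constant across all samples
      p[i] <- 1; constant[i] <- TRUE
    } else {
      p[i] <- suppressWarnings(
        stats::wilcox.test(x, y, exact = TRUE,
                           alternative = "two.sided")$p.value)
    }
  }
  adj <- stats::p.adjust(p, method = "BH")
  hi <- pmax(med_a, med_b) + pseudo_count
  lo <- pmin(med_a, med_b) + pseudo_count
  fc <- ifelse(lo > 0, hi / lo, Inf)
  direction <- ifelse(med_a == med_b, "equal",
                      ifelse(med_a > med_b, lev[1], lev[2]))
  out <- data.frame(feature = rownames(mat) %||% as.character(seq_len(n)),
                    median_1 = med_a, median_2 = med_b,
                    fold_change = fc, direction = direction,
                    p_value = p, adj_p = adj,
                    significant = fc > fc_threshold & adj < alpha,
                    constant = constant, stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("median_", lev)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Bray-Curtis dissimilarities between samples
#'
#' BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum x + sum y), computed with
#' \code{vegan::vegdist}; samples are the columns of the matrix.
#'
#' @param mat features x samples non-negative matrix.
#' @return symmetric square matrix of dissimilarities in [0, 1] with zero
#'   diagonal.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("Bray-Curtis requires non-negative values")
  zero <- colSums(mat) == 0
  if (sum(zero) >= 2L)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(mat)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(t(mat), method = "bray"))
}

#' Export a heat-tree-ready differential table
#'
#' One row per taxon at the results' rank, with its full canonical lineage
#' string, per-group median scaled abundance, adjusted p and direction —
#' consumable by external heat-tree / ordination plotting tools.
#'
#' @param results output of \code{\link{wilcoxon_bh}} whose features are
#'   taxids at one rank.
#' @param tree \code{taxonomy_tree}.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
export_heat_tree_table <- function(results, tree, path) {
  lin <- vapply(results$feature, function(f) {
    l <- lineage(tree, as.integer(f))
    paste(tax_name(tree, l[!is.na(l)]), collapse = ";")
  }, character(1))
  out <- cbind(data.frame(taxid = results$feature, lineage = lin,
                          stringsAsFactors = FALSE),
               results[, setdiff(names(results), "feature")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
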