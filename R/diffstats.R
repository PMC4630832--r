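#' Gene-by-sample abundance matrix
#'
#' Container for the differential-gene stage: a matrix of mapped-read counts
#' (genes x samples), per-sample total read counts, and a two-level group
#' label per sample. Column sums may exceed or fall short of the totals
#' (multi-mapping and unmapped reads are both allowed); totals must be
#' positive.
#'
#' @param counts non-negative integer matrix, genes in rows.
#' @param totals per-sample total read counts (length = ncol(counts)).
#' @param groups per-sample group labels (exactly two distinct values).
#' @return an object of class \code{abundance_matrix}.
#' @export
abundance_matrix <- function(counts, totals, groups) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(totals) != ncol(counts))
    stop("one total per sample is required")
  if (any(totals <= 0)) stop("totals must be positive")
  if (length(groups) != ncol(counts))
    stop("one group label per sample is required")
  if (length(unique(groups)) != 2)
    stop("exactly two groups are required")
  structure(list(counts = counts, totals = as.numeric(totals),
                 groups = as.character(groups)),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("abundance_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Read an abundance matrix from TSV files
#'
#' \code{counts_tsv}: gene x sample counts with gene ids in the first column
#' and sample ids as header. \code{samples_tsv}: columns \code{sample},
#' \code{total}, \code{group}.
#'
#' @param counts_tsv,samples_tsv file paths.
#' @return an \code{abundance_matrix}.
#' @export
read_abundance_matrix <- function(counts_tsv, samples_tsv) {
  counts <- read.delim(counts_tsv, row.names = 1, check.names = FALSE)
  meta <- read.delim(samples_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "total", "group") %in% names(meta)))
  idx <- match(colnames(counts), meta$sample)
  if (anyNA(idx)) stop("samples file does not cover every count column")
  abundance_matrix(as.matrix(counts), meta$total[idx], meta$group[idx])
}

#' Reads-per-billion normalization
#'
#' Scales a mapped-read count by 1e9 / total reads of its sample, the
#' abundance unit used for cross-sample gene comparison.
#'
#' @param count mapped-read count(s).
#' @param sample_total total reads in the sample, > 0.
#' @return normalized abundance (reads per billion).
#' @export
normalize_per_billion <- function(count, sample_total) {
  if (any(sample_total <= 0)) stop("sample_total must be positive")
  count / sample_total * 1e9
}

#' One-sided Wilcoxon rank-sum p-value
#'
#' Tests whether the values of \code{x} are stochastically greater than
#' those of \code{y}. The p-value is exact (full enumeration of the
#' rank-sum distribution) when \code{length(x) + length(y) <= 12} and there
#' are no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return p-value for the alternative "x greater".
#' @export
wilcoxon_one_sided <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 12) && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = use_exact,
                correct = TRUE)$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: monotone over the sorted p-values, each
#' bounded by 1, never below the raw p-value.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values in input order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Select genes enriched in group 1
#'
#' Normalizes every gene to reads per billion, tests group 1 > group 2 with
#' the one-sided Wilcoxon rank-sum test, adjusts with Benjamini-Hochberg,
#' and returns genes with q below the threshold, sorted by q and then by the
#' difference of group medians (largest effect first).
#'
#' @param matrix an \code{abundance_matrix}; the first group label
#'   encountered (or \code{group1}) is the enriched side.
#' @param q_threshold FDR threshold (default 0.01).
#' @param group1 optional explicit label of the enriched group.
#' @return data frame with one row per selected gene: \code{gene}, \code{p},
#'   \code{q}, \code{median1}, \code{median2}, \code{effect}; attribute
#'   \code{"all"} carries the full per-gene table.
#' @export
select_enriched <- function(matrix, q_threshold = 0.01, group1 = NULL) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (is.null(group1)) group1 <- matrix$groups[1]
  in1 <- matrix$groups == group1
  if (!any(in1) || all(in1)) stop("group1 must match some but not all samples")
  empty <- data.frame(gene = character(0), p = numeric(0), q = numeric(0),
                      median1 = numeric(0), median2 = numeric(0),
                      effect = numeric(0), stringsAsFactors = FALSE)
  if (nrow(matrix$counts) == 0) return(empty)
  norm <- sweep(matrix$counts, 2, matrix$totals, "/") * 1e9
  p <- apply(norm, 1, function(v) wilcoxon_one_sided(v[in1], v[!in1]))
  q <- fdr_adjust(p)
  med1 <- apply(norm[, in1, drop = FALSE], 1, median)
  med2 <- apply(norm[, !in1, drop = FALSE], 1, median)
  all_tab <- data.frame(gene = rownames(matrix$counts), p = p, q = q,
                        median1 = med1, median2 = med2,
                        effect = med1 - med2, stringsAsFactors = FALSE)
  rownames(all_tab) <- NULL
  sel <- all_tab[all_tab$q < q_threshold, , drop = FALSE]
  sel <- sel[order(sel$q, -sel$effect), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all") <- all_tab
  sel
}
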