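#' Sensitivity and precision of a read extraction
#'
#' Scores an extraction against read provenance: sensitivity is the fraction
#' of target-genome reads that were extracted, precision the fraction of
#' extracted reads that came from a target genome. Empty denominators give
#' \code{NA} (undefined), never 0.
#'
#' @param extracted_ids ids of the extracted reads.
#' @param provenance data frame mapping \code{id} to \code{genome} (as from
#'   \code{\link{parse_provenance}}); must cover every read of the run.
#' @param target_genomes character vector of target genome ids.
#' @return list with \code{sensitivity}, \code{precision}, the underlying
#'   counts, and \code{per_genome} (per-genome extracted/total counts and
#'   sensitivity).
#' @export
extraction_metrics <- function(extracted_ids, provenance, target_genomes) {
  stopifnot(is.data.frame(provenance),
            all(c("id", "genome") %in% names(provenance)))
  if (!all(extracted_ids %in% provenance$id))
    stop("provenance must cover every extracted read")
  is_target <- provenance$genome %in% target_genomes
  extracted <- provenance$id %in% extracted_ids
  tp <- sum(extracted & is_target)
  n_target <- sum(is_target)
  n_extracted <- sum(extracted)
  per <- do.call(rbind, lapply(split(extracted, provenance$genome),
                               function(e) data.frame(n_reads = length(e),
                                                      n_extracted = sum(e))))
  per$genome <- rownames(per)
  per$sensitivity <- ifelse(per$n_reads > 0,
                            per$n_extracted / per$n_reads, NA_real_)
  rownames(per) <- NULL
  list(
    sensitivity = if (n_target > 0) tp / n_target else NA_real_,
    precision = if (n_extracted > 0) tp / n_extracted else NA_real_,
    n_target = n_target, n_extracted = n_extracted, n_true_positive = tp,
    per_genome = per[, c("genome", "n_reads", "n_extracted", "sensitivity")])
}

#' Assembly contig statistics
#'
#' Filters contigs below \code{min_len} (300 bp by default, the reporting
#' convention for subtractive assemblies), then computes the contig count,
#' total length, N50 (the length of the contig at which the descending
#' cumulative length first reaches half the filtered total, inclusive), the
#' largest contig, and the sorted cumulative-length curve.
#'
#' @param contigs a FASTA path, named character vector, or
#'   \code{DNAStringSet}.
#' @param min_len minimum contig length retained (default 300).
#' @return list with \code{n_contigs}, \code{total_length}, \code{n50},
#'   \code{largest} and \code{cumulative} (non-decreasing, ends at the
#'   total).
#' @export
contig_stats <- function(contigs, min_len = 300) {
  seqs <- read_fasta_sequences(contigs)
  lens <- nchar(seqs)
  lens <- lens[lens >= min_len]
  if (length(lens) == 0) {
    warning("no contigs of at least ", min_len, " bp")
    return(list(n_contigs = 0L, total_length = 0, n50 = 0, largest = 0,
                cumulative = numeric(0)))
  }
  lens <- sort(unname(lens), decreasing = TRUE)
  cum <- cumsum(as.numeric(lens))
  n50 <- lens[which(cum >= cum[length(cum)] / 2)[1]]
  list(n_contigs = length(lens), total_length = cum[length(cum)],
       n50 = n50, largest = lens[1], cumulative = cum)
}

#' Anchor-based genome fraction
#'
#' Fraction of reference positions covered by contigs, computed by exact
#' k-mer anchoring rather than alignment: a reference position is covered
#' when it lies inside a window whose canonical \code{anchor_k}-mer also
#' occurs in some contig. For error-free contigs this equals the
#' alignment-based genome fraction up to the k-1 positions flanking each
#' covered segment's ends; with sequencing errors it is a conservative proxy
#' (it is not a reimplementation of an aligner-based evaluator).
#'
#' @param contigs contig sequences (FASTA path, named vector, or
#'   \code{DNAStringSet}).
#' @param reference reference genome, same accepted forms; multiple records
#'   are scored jointly (covered bases over total bases).
#' @param anchor_k anchor k-mer length (default 31).
#' @return fraction in \[0, 1\].
#' @export
genome_fraction <- function(contigs, reference, anchor_k = 31) {
  contigs <- read_fasta_sequences(contigs)
  reference <- read_fasta_sequences(reference)
  anchor_k <- as.integer(anchor_k)
  if (anchor_k < 15 || anchor_k > 31)
    stop("anchor_k must be within [15, 31]")
  if (all(nchar(contigs) < anchor_k))
    stop("anchor_k exceeds every contig length")
  anchors <- sk_distinct_kmers(contigs, anchor_k)
  covered <- 0
  total <- 0
  for (ref in reference) {
    len <- nchar(ref)
    total <- total + len
    if (len < anchor_k) next
    memb <- sk_window_membership(ref, anchors, anchor_k)
    hit <- !is.na(memb) & memb == 1L
    if (!any(hit)) next
    # a hit window at start j covers positions j .. j+k-1
    cov <- logical(len)
    starts <- which(hit)
    delta <- integer(len + 1)
    delta[starts] <- delta[starts] + 1L
    ends <- pmin(starts + anchor_k, len + 1L)
    delta[ends] <- delta[ends] - 1L
    cov <- cumsum(delta[seq_len(len)]) > 0
    covered <- covered + sum(cov)
  }
  covered / total
}

#' Expected fraction of differentially covered bases
#'
#' Models the per-base coverages of one genome in two samples as independent
#' Poisson variables with means \code{depthA} and \code{depthB}, and returns
#' the probability that a base is covered at least \code{ratio} times more
#' deeply in A than in B: P(X >= ratio * Y) summed over the Y distribution,
#' truncated once the remaining tail mass of Y drops below
#' \code{tail_cutoff}. With \code{depthB = 0} every base qualifies
#' (probability 1).
#'
#' @param depthA,depthB mean per-base coverages, > 0 (depthB = 0 allowed as a
#'   limit).
#' @param ratio required coverage ratio (default 2).
#' @param tail_cutoff truncation mass (default 1e-12).
#' @return probability in \[0, 1\].
#' @export
expected_diff_base_fraction <- function(depthA, depthB, ratio = 2,
                                        tail_cutoff = 1e-12) {
  stopifnot(depthA > 0, depthB >= 0, ratio >= 1)
  if (depthB == 0) return(1)
  # smallest ymax with remaining upper-tail mass below the cutoff
  ymax <- depthB
  while (ppois(ymax, depthB, lower.tail = FALSE) >= tail_cutoff)
    ymax <- ymax + max(10, ceiling(depthB))
  y <- 0:ymax
  # P(X >= ratio*y) = P(X > ceiling(ratio*y) - 1)
  sum(dpois(y, depthB) * ppois(ceiling(ratio * y) - 1, depthA,
                               lower.tail = FALSE))
}
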