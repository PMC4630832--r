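#' Distinctive-read test
#'
#' A read is distinctive against a signature set when at least a fraction
#' \code{p} (default 50 \%) of its valid (ACGT-only) k-mer windows are
#' signature members. At least one signature window is required even at
#' \code{p = 0}, and reads shorter than k (no valid windows) are never
#' distinctive. The fraction test is evaluated as \code{D >= ceiling(p * V)}
#' with a half-ulp guard so the inclusive boundary is exact.
#'
#' @param reads read sequences (any form accepted by \code{\link{count_kmers}}).
#' @param signature a \code{signature_set}.
#' @param p required fraction of signature windows, in \[0, 1\].
#' @return logical vector, one element per read.
#' @export
is_distinctive <- function(reads, signature, p = 0.5) {
  stopifnot(inherits(signature, "signature_set"), p >= 0, p <= 1)
  seqs <- as_sequences(reads)
  hits <- sk_signature_hits(seqs, signature$kmers, signature$k)
  distinctive_from_counts(hits$hits, hits$valid, p)
}

distinctive_from_counts <- function(D, V, p) {
  need <- ceiling(p * V - 1e-9) # guard against upward rounding of p*V
  V >= 1L & D >= 1L & D >= need
}

#' Extract distinctive reads
#'
#' Returns exactly the reads for which \code{\link{is_distinctive}} holds,
#' preserving input order. With \code{pair_mode = "both"}, mates are located
#' by stripping a trailing \code{/1} or \code{/2} from the read id and a read
#' is also extracted when its mate qualifies (assemblers exploit intact
#' pairs).
#'
#' @param reads a read-set data frame (or any read source; bare sequence
#'   vectors are wrapped with synthetic ids).
#' @param signature a \code{signature_set}.
#' @param p required fraction of signature windows.
#' @param pair_mode \code{"both"} (default) or \code{"independent"}.
#' @return the subset of \code{reads} (same columns) that qualifies.
#' @export
extract_reads <- function(reads, signature, p = 0.5,
                          pair_mode = c("both", "independent")) {
  pair_mode <- match.arg(pair_mode)
  reads <- as_read_set(reads)
  keep <- is_distinctive(reads$sequence, signature, p)
  if (pair_mode == "both" && any(grepl("/[12]$", reads$id))) {
    frag <- sub("/[12]$", "", reads$id)
    keep <- keep | frag %in% frag[keep]
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_read_set <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("id", "sequence") %in% names(reads)))
    return(reads)
  }
  seqs <- as_sequences(reads)
  data.frame(id = sprintf("read%06d", seq_along(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Iterative stratified extraction over a threshold ladder
#'
#' When the true compositional difference between two groups is unknown,
#' reads are extracted iteratively over a ladder of thresholds -- first
#' against the unique k-mers of group A, then against the differential sets
#' at ratios 10, 8, 6, 4, 2. Each read is assigned to the first (most
#' stringent) rung at which it is distinctive and is removed from
#' consideration for later rungs, so the strata are pairwise disjoint; by the
#' nesting of signature sets their union equals a single-pass extraction at
#' the smallest ratio of the ladder.
#'
#' @param reads reads of group A (read-set data frame or sequence source).
#' @param tableA,tableB pooled \code{kmer_count_table}s of groups A and B.
#' @param p required fraction of signature windows.
#' @param ladder thresholds, \code{"unique"} first then strictly decreasing
#'   ratios.
#' @param direction label stored on the strata.
#' @return an object of class \code{extraction_strata}: a list of strata,
#'   each with \code{label}, \code{direction} and \code{reads} (the read
#'   subset assigned to that rung).
#' @export
iterative_extract <- function(reads, tableA, tableB, p = 0.5,
                              ladder = c("unique", 10, 8, 6, 4, 2),
                              direction = "A_minus_B") {
  check_table_pair(tableA, tableB)
  ladder <- as.character(ladder)
  ratios <- suppressWarnings(as.numeric(ladder[ladder != "unique"]))
  if (anyNA(ratios) || is.unsorted(rev(ratios), strictly = TRUE))
    stop("ladder must be 'unique' followed by strictly decreasing ratios")
  reads <- as_read_set(reads)
  assigned <- rep(NA_character_, nrow(reads))
  strata <- vector("list", length(ladder))
  names(strata) <- ladder
  for (lab in ladder) {
    sig <- signature_at(tableA, tableB,
                        if (lab == "unique") "unique" else as.numeric(lab),
                        direction)
    open <- is.na(assigned)
    qual <- rep(FALSE, nrow(reads))
    if (any(open))
      qual[open] <- is_distinctive(reads$sequence[open], sig, p)
    assigned[qual] <- lab
    sub <- reads[qual, , drop = FALSE]
    rownames(sub) <- NULL
    strata[[lab]] <- list(label = lab, direction = direction, reads = sub)
  }
  structure(strata, class = "extraction_strata")
}

#' @export
print.extraction_strata <- function(x, ...) {
  m <- strata_manifest(x)
  cat("iterative extraction strata:\n")
  print(m, row.names = FALSE)
  invisible(x)
}

#' Per-stratum read counts and base totals
#'
#' One row per threshold rung with the number of reads and the gigabases
#' extracted at that rung -- the summary shape used for pooled case/control
#' comparisons.
#'
#' @param strata an \code{extraction_strata} object.
#' @return data frame with columns \code{direction}, \code{threshold},
#'   \code{n_reads}, \code{gigabases}.
#' @export
strata_manifest <- function(strata) {
  data.frame(
    direction = vapply(strata, function(s) s$direction, ""),
    threshold = vapply(strata, function(s) s$label, ""),
    n_reads = vapply(strata, function(s) nrow(s$reads), 0),
    gigabases = vapply(strata, function(s) sum(nchar(s$reads$sequence)) / 1e9,
                       0),
    stringsAsFactors = FALSE)
}

#' All reads of an extraction, pooled across strata
#'
#' @param strata an \code{extraction_strata} object.
#' @return a read-set data frame (concatenation of all strata, ladder order).
#' @export
strata_reads <- function(strata) {
  out <- do.call(rbind, lapply(strata, function(s) s$reads))
  rownames(out) <- NULL
  out
}
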