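#' Per-base normalized k-mer frequency
#'
#' K-mer counts are normalized by the total bases of the dataset they came
#' from, so that ratios between datasets of different sizes are not biased
#' toward the larger dataset.
#'
#' @param count k-mer count(s), >= 0.
#' @param total_bases total bases in the source dataset, > 0.
#' @return \code{count / total_bases}.
#' @export
normalized_frequency <- function(count, total_bases) {
  if (any(total_bases <= 0)) stop("total_bases must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / total_bases
}

new_signature_set <- function(kmers, k, direction, threshold) {
  structure(list(direction = direction, threshold = threshold,
                 kmers = kmers, k = as.integer(k)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %s at threshold %s, %s k-mers (k = %d)\n",
              x$direction, as.character(x$threshold),
              format(length(x$kmers), big.mark = ","), x$k))
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$kmers)

#' Differential k-mers between two count tables
#'
#' A k-mer of table A is differential at ratio threshold \code{r} when its
#' per-base normalized frequency in A is at least \code{r} times its
#' frequency in B (inclusive comparison). A k-mer absent from B has frequency
#' zero there and qualifies at every r. The comparison is done by
#' cross-multiplication of integer counts and totals
#' (\code{cA * basesB >= r * cB * basesA}), which is exact at the inclusive
#' boundary for any desk-scale input.
#'
#' @param tableA,tableB \code{kmer_count_table}s with equal k.
#' @param r ratio threshold, >= 1.
#' @param direction label stored on the result (default \code{"A_minus_B"}).
#' @return a \code{signature_set} holding the qualifying k-mers of A.
#' @export
differential_kmers <- function(tableA, tableB, r, direction = "A_minus_B") {
  check_table_pair(tableA, tableB)
  if (!is.numeric(r) || length(r) != 1 || r < 1) stop("r must be >= 1")
  cB <- match_counts(tableA$kmer, tableB)
  keep <- tableA$count * tableB$total_bases >= r * cB * tableA$total_bases
  new_signature_set(tableA$kmer[keep], tableA$k, direction, r)
}

#' K-mers unique to one count table
#'
#' K-mers present (at multiplicity >= 2, after singleton exclusion) in table
#' A but absent from table B.
#'
#' @inheritParams differential_kmers
#' @return a \code{signature_set} with threshold \code{"unique"}.
#' @export
unique_kmers <- function(tableA, tableB, direction = "A_minus_B") {
  check_table_pair(tableA, tableB)
  keep <- !(tableA$kmer %in% tableB$kmer)
  new_signature_set(tableA$kmer[keep], tableA$k, direction, "unique")
}

#' Signature set at a rung of the iterative ladder
#'
#' Dispatches to \code{\link{unique_kmers}} when \code{threshold} is the
#' string \code{"unique"} and to \code{\link{differential_kmers}} otherwise.
#'
#' @inheritParams differential_kmers
#' @param threshold numeric ratio or \code{"unique"}.
#' @export
signature_at <- function(tableA, tableB, threshold,
                         direction = "A_minus_B") {
  if (identical(threshold, "unique"))
    unique_kmers(tableA, tableB, direction)
  else
    differential_kmers(tableA, tableB, as.numeric(threshold), direction)
}

check_table_pair <- function(tableA, tableB) {
  stopifnot(inherits(tableA, "kmer_count_table"),
            inherits(tableB, "kmer_count_table"))
  if (tableA$k != tableB$k)
    stop("count tables disagree on k (", tableA$k, " vs ", tableB$k, ")")
  if (tableA$total_bases <= 0 || tableB$total_bases <= 0)
    stop("count tables must have positive total_bases")
  invisible(TRUE)
}

match_counts <- function(kmers, table) {
  idx <- match(kmers, table$kmer)
  counts <- table$count[idx]
  counts[is.na(idx)] <- 0
  counts
}

#' Write / read a signature set
#'
#' One canonical k-mer per line, preceded by a header line recording the
#' direction, threshold and k.
#'
#' @param sig a \code{signature_set}.
#' @param path file path.
#' @export
write_signature_set <- function(sig, path) {
  stopifnot(inherits(sig, "signature_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#direction=%s\tthreshold=%s\tk=%d",
                     sig$direction, as.character(sig$threshold), sig$k), con)
  if (length(sig$kmers)) writeLines(sig$kmers, con)
  invisible(path)
}

#' @rdname write_signature_set
#' @export
read_signature_set <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#direction="))
    stop("not a signature-set file: ", path)
  fields <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  vals <- setNames(sub("^[^=]*=", "", fields), sub("=.*$", "", fields))
  thr <- vals[["threshold"]]
  if (thr != "unique") thr <- as.numeric(thr)
  new_signature_set(lines[-1], as.integer(vals[["k"]]),
                    vals[["direction"]], thr)
}

#' Manifest of signature sets
#'
#' Summarizes a list of \code{signature_set}s as one row per set (direction,
#' threshold, number of k-mers) -- the shape used to report read extraction
#' per threshold rung.
#'
#' @param sets list of \code{signature_set}s.
#' @return data frame with columns \code{direction}, \code{threshold},
#'   \code{n_kmers}.
#' @export
signature_manifest <- function(sets) {
  data.frame(
    direction = vapply(sets, function(s) s$direction, ""),
    threshold = vapply(sets, function(s) as.character(s$threshold), ""),
    n_kmers = vapply(sets, function(s) length(s$kmers), 0),
    stringsAsFactors = FALSE)
}
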