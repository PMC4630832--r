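#' Canonical form of DNA windows
#'
#' Maps each window of length \code{k} to the lexicographically smaller of the
#' window and its reverse complement (A < C < G < T), so that both strands of
#' a k-mer share a single key. Windows containing any character outside
#' \code{ACGT} (case-insensitive) have no canonical form and yield \code{NA}.
#'
#' @param windows character vector of DNA windows, all of length \code{k}.
#' @param k window length; defaults to the length of the first window.
#' @return character vector of canonical k-mers (uppercase), \code{NA} where a
#'   window contains an ambiguous base.
#' @examples
#' encode_canonical(c("ACGT", "TTTT", "ACNT"))
#' @export
encode_canonical <- function(windows, k = nchar(windows[1])) {
  stopifnot(is.character(windows), length(windows) >= 1)
  if (any(nchar(windows) != k))
    stop("all windows must have length k = ", k)
  sk_encode_canonical(windows, as.integer(k))
}

#' Optimal number of bloom-filter hash functions
#'
#' For a bloom filter of \code{m} bits expected to hold \code{n} distinct
#' elements, the false-positive rate is minimized at d = (m/n) ln 2 hash
#' functions; the result is rounded to the nearest integer and floored at 1.
#'
#' @param m number of bits in the filter.
#' @param n expected number of distinct elements.
#' @return integer number of hash functions, >= 1.
#' @export
optimal_hash_count <- function(m, n) {
  if (!is.numeric(m) || !is.numeric(n) || any(m < 1) || any(n < 1))
    stop("m and n must be positive")
  pmax(1L, as.integer(round(m / n * log(2))))
}

#' Size a bloom filter for a target false-positive rate
#'
#' Standard sizing: m = ceiling(-n ln f / (ln 2)^2) bits and
#' d = \code{\link{optimal_hash_count}}(m, n) hash functions.
#'
#' @param n expected number of distinct elements.
#' @param fpr target false-positive rate (default 0.01).
#' @return list with elements \code{m} and \code{d}.
#' @export
bloom_parameters <- function(n, fpr = 0.01) {
  stopifnot(n >= 1, fpr > 0, fpr < 1)
  m <- ceiling(-n * log(fpr) / log(2)^2)
  list(m = m, d = optimal_hash_count(m, n))
}

#' Create a bloom filter
#'
#' A fixed-size bit array with \code{d} seeded hash functions. Membership
#' queries have no false negatives; false positives occur with a probability
#' governed by the load (approximately \code{(1 - exp(-d n / m))^d} after
#' \code{n} distinct insertions). Either give \code{m} and \code{d} directly,
#' or give \code{n} (and optionally \code{fpr}) to size the filter.
#'
#' The filter is a reference object: \code{\link{bloom_insert}} modifies it in
#' place and returns it invisibly.
#'
#' @param m number of bits.
#' @param d number of hash functions.
#' @param n expected number of distinct elements (alternative to \code{m}).
#' @param fpr target false-positive rate used with \code{n}.
#' @return an object of class \code{bloom_filter}.
#' @export
bloom_filter <- function(m = NULL, d = NULL, n = NULL, fpr = 0.01) {
  if (is.null(m)) {
    if (is.null(n)) stop("give either m (and d) or n")
    par <- bloom_parameters(n, fpr)
    m <- par$m
    if (is.null(d)) d <- par$d
  }
  if (is.null(d)) stop("d is required when m is given without n")
  if (m < 1 || d < 1) stop("m and d must be >= 1")
  obj <- new.env(parent = emptyenv())
  obj$ptr <- sk_bloom_new(as.numeric(m), as.integer(d))
  obj$m <- as.numeric(m)
  obj$d <- as.integer(d)
  class(obj) <- "bloom_filter"
  obj
}

#' @rdname bloom_filter
#' @param bf a \code{bloom_filter}.
#' @param kmers character vector of k-mers (one common length per call).
#' @export
bloom_insert <- function(bf, kmers) {
  stopifnot(inherits(bf, "bloom_filter"), is.character(kmers))
  sk_bloom_insert(bf$ptr, kmers, nchar(kmers[1]))
  invisible(bf)
}

#' @rdname bloom_filter
#' @export
bloom_contains <- function(bf, kmers) {
  stopifnot(inherits(bf, "bloom_filter"), is.character(kmers))
  sk_bloom_contains(bf$ptr, kmers, nchar(kmers[1]))
}

#' @export
print.bloom_filter <- function(x, ...) {
  info <- sk_bloom_info(x$ptr)
  cat(sprintf("bloom filter: m = %s bits, d = %d, %s insertions, load %.3f\n",
              format(info$m, big.mark = ","), info$d,
              format(info$n_inserted, big.mark = ","),
              info$bits_set / info$m))
  invisible(x)
}

#' Count canonical k-mers seen at least twice
#'
#' Streams every valid window of every read through a bloom filter: a k-mer's
#' first sighting is recorded only in the filter; a re-sighting opens a slot
#' in the count table. A second pass recounts the tabled k-mers exactly and
#' drops entries whose true multiplicity is 1 (bloom false-positive
#' admissions). The result therefore equals a naive exact count with
#' singletons removed -- singleton exclusion discards the error-dominated
#' tail of the k-mer spectrum at a fraction of the memory.
#'
#' @param reads character vector of read sequences, a
#'   \code{Biostrings::DNAStringSet}, a read-set data frame from
#'   \code{\link{read_reads}}, or a vector of FASTA/FASTQ file paths
#'   (optionally gzipped).
#' @param k k-mer length, 15--31 (default 25).
#' @param expected_kmers expected number of distinct k-mers, used to size the
#'   bloom filter; defaults to the total window count of the input (a safe
#'   upper bound).
#' @param fpr target bloom false-positive rate (default 0.01).
#' @param bloom_m,bloom_d explicit bloom geometry, overriding
#'   \code{expected_kmers}/\code{fpr}.
#' @return an object of class \code{kmer_count_table}: a list with elements
#'   \code{k}, \code{kmer} (sorted canonical strings), \code{count}
#'   (multiplicities, all >= 2), \code{total_bases} (sum of all read lengths,
#'   including reads shorter than k) and \code{total_reads}.
#' @examples
#' count_kmers(c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT"), k = 15)
#' @export
count_kmers <- function(reads, k = 25, expected_kmers = NULL, fpr = 0.01,
                        bloom_m = NULL, bloom_d = NULL) {
  k <- as.integer(k)
  if (k < 15L || k > 31L) stop("k must be within [15, 31]")
  reads <- as_sequences(reads)
  if (is.null(bloom_m) || is.null(bloom_d)) {
    if (is.null(expected_kmers)) {
      expected_kmers <- max(1, sum(pmax(0, nchar(reads) - k + 1)))
    }
    par <- bloom_parameters(expected_kmers, fpr)
    bloom_m <- par$m
    bloom_d <- par$d
  }
  res <- sk_count_kmers(reads, k, as.numeric(bloom_m), as.integer(bloom_d))
  new_kmer_count_table(k, res$kmer, res$count, res$total_bases, res$total_reads)
}

new_kmer_count_table <- function(k, kmer, count, total_bases, total_reads) {
  structure(list(k = as.integer(k), kmer = kmer, count = as.numeric(count),
                 total_bases = as.numeric(total_bases),
                 total_reads = as.numeric(total_reads)),
            class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf(
    "kmer_count_table: k = %d, %s k-mers (count >= 2), %s bases in %s reads\n",
    x$k, format(length(x$kmer), big.mark = ","),
    format(x$total_bases, big.mark = ","),
    format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' @export
length.kmer_count_table <- function(x) length(x$kmer)

# Coerce the accepted read inputs to a plain character vector of sequences.
as_sequences <- function(reads) {
  if (is.character(reads)) {
    if (length(reads) > 0 && all(file.exists(reads)) &&
        !any(grepl("^[ACGTNacgtn]+$", reads))) {
      return(read_reads(reads)$sequence)
    }
    return(reads)
  }
  if (inherits(reads, "DNAStringSet")) return(as.character(reads))
  if (is.data.frame(reads) && "sequence" %in% names(reads))
    return(reads$sequence)
  stop("unsupported read source; give sequences, a DNAStringSet, ",
       "a read-set data frame, or file paths")
}

#' Write / read a k-mer count table as TSV
#'
#' Plain-text dump: a header line \code{#k=..<TAB>total_bases=..<TAB>}
#' \code{total_reads=..} followed by \code{kmer<TAB>count} rows (canonical
#' uppercase k-mer strings).
#'
#' @param table a \code{kmer_count_table}.
#' @param path output (input) file path.
#' @return \code{read_count_table} returns a \code{kmer_count_table};
#'   \code{write_count_table} returns \code{path} invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d\ttotal_bases=%.0f\ttotal_reads=%.0f",
                     table$k, table$total_bases, table$total_reads), con)
  if (length(table$kmer))
    writeLines(paste(table$kmer, format(table$count, scientific = FALSE,
                                        trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#k="))
    stop("not a count-table file: ", path)
  fields <- strsplit(sub("^#", "", header), "\t")[[1]]
  meta <- setNames(
    as.numeric(sub("^[^=]*=", "", fields)),
    sub("=.*$", "", fields))
  lines <- readLines(path)
  body <- if (length(lines) > 1) {
    read.delim(text = lines[-1], header = FALSE,
               colClasses = c("character", "numeric"),
               col.names = c("kmer", "count"))
  } else {
    data.frame(kmer = character(0), count = numeric(0))
  }
  new_kmer_count_table(meta[["k"]], body$kmer, body$count,
                       meta[["total_bases"]], meta[["total_reads"]])
}
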