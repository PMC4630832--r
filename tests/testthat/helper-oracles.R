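# Independent oracles, deliberately written without the package's fast paths:
# plain-R reverse complement, dictionary k-mer counting, rank-sum enumeration,
# and a direct Poisson double sum.

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

canonical_chr <- function(windows) {
  rc <- rc_chr(windows)
  ifelse(windows <= rc, windows, rc) # ACGT-only input; C-locale-safe letters
}

all_windows <- function(read, k) {
  n <- nchar(read)
  if (n < k) return(character(0))
  substring(read, 1:(n - k + 1), k:n)
}

# Exact dictionary count of canonical k-mers with singletons removed.
naive_kmer_count <- function(reads, k) {
  wins <- unlist(lapply(reads, all_windows, k = k), use.names = FALSE)
  wins <- toupper(wins[grepl("^[ACGTacgt]+$", wins)])
  if (length(wins) == 0)
    return(list(kmer = character(0), count = numeric(0)))
  tab <- table(canonical_chr(wins))
  tab <- tab[tab >= 2]
  ord <- order(names(tab))
  list(kmer = names(tab)[ord], count = as.numeric(tab)[ord])
}

random_reads <- function(n, len_range = c(40, 80), n_rate = 0) {
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    alph <- c("A", "C", "G", "T")
    s <- sample(alph, len, replace = TRUE)
    if (n_rate > 0) {
      hit <- runif(len) < n_rate
      s[hit] <- "N"
    }
    paste(s, collapse = "")
  }, "")
}

random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, "")
}

# Exact one-sided rank-sum p-value by full enumeration of all C(n1+n2, n1)
# group assignments of the observed pooled values (ties included naturally).
enum_wilcox_greater <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  stat <- apply(sets, 2, function(idx) sum(r[idx]))
  mean(stat >= obs)
}

# High-precision truncated double sum for P(X >= ratio * Y),
# X ~ Pois(dA), Y ~ Pois(dB); formulated without ppois.
poisson_diff_oracle <- function(dA, dB, ratio, ymax = 400, xmax = 800) {
  py <- dpois(0:ymax, dB)
  px <- dpois(0:xmax, dA)
  sum(vapply(0:ymax, function(y) {
    xmin <- ceiling(ratio * y)
    py[y + 1] * if (xmin > xmax) 0 else sum(px[(xmin + 1):(xmax + 1)])
  }, 0))
}

# Directly constructed count table (bypasses counting) for algebra tests.
manual_table <- function(kmers, counts, total_bases, k = nchar(kmers[1]),
                         total_reads = 1) {
  stopifnot(length(kmers) == length(counts))
  ord <- order(kmers)
  subkmer:::new_kmer_count_table(k, kmers[ord], counts[ord], total_bases,
                                 total_reads)
}
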