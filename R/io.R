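#' Read sequencing reads from FASTA/FASTQ files
#'
#' Accepts plain or gzip-compressed FASTA and FASTQ; the format of each file
#' is sniffed from its first character. Multiple files are concatenated in
#' the order given, which is how a pooled sample group is formed. FASTQ
#' qualities are carried along verbatim (and ignored by the k-mer machinery).
#'
#' @param files character vector of file paths.
#' @return a data frame with columns \code{id}, \code{sequence} and
#'   \code{quality} (\code{NA} for FASTA records).
#' @export
read_reads <- function(files) {
  stopifnot(length(files) >= 1, all(file.exists(files)))
  parts <- lapply(files, function(f) {
    fmt <- sniff_format(f)
    if (fmt == "fastq") {
      # Biostrings warns that FASTQ metadata columns are dropped on
      # conversion; ids, sequences and qualities are all we carry
      x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(f))
      data.frame(id = names(x), sequence = as.character(x),
                 quality = as.character(Biostrings::quality(x)),
                 stringsAsFactors = FALSE)
    } else {
      x <- Biostrings::readDNAStringSet(f, format = "fasta")
      data.frame(id = names(x), sequence = as.character(x),
                 quality = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (length(first) == 0) stop("empty file: ", path)
  if (startsWith(first, "@")) "fastq"
  else if (startsWith(first, ">")) "fasta"
  else stop("cannot determine format of ", path)
}

#' Write reads to FASTA or FASTQ
#'
#' Format follows the file extension (\code{.fq}/\code{.fastq} write FASTQ,
#' anything else FASTA); a trailing \code{.gz} compresses. Reads lacking a
#' quality string are written with a constant quality of \code{"I"} when
#' FASTQ output is requested.
#'
#' @param reads a read-set data frame (\code{id}, \code{sequence}, optional
#'   \code{quality}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_reads <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  compress <- grepl("\\.gz$", path)
  base <- sub("\\.gz$", "", path)
  fastq <- grepl("\\.(fq|fastq)$", base)
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  if (fastq) {
    qual <- reads$quality
    if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
    missing_q <- is.na(qual)
    qual[missing_q] <- vapply(nchar(reads$sequence[missing_q]),
                              function(n) strrep("I", n), "")
    qualities <- Biostrings::BStringSet(qual)
    # Biostrings notes that per-record metadata is dropped on FASTQ output;
    # nothing we keep lives there
    suppressWarnings(
      Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                  qualities = qualities, compress = compress))
  } else {
    Biostrings::writeXStringSet(seqs, path, format = "fasta",
                                compress = compress)
  }
  invisible(path)
}

#' Read contigs or reference genomes from FASTA
#'
#' @param x a FASTA path, a named character vector of sequences, or a
#'   \code{DNAStringSet}.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    set <- Biostrings::readDNAStringSet(x, format = "fasta")
    return(setNames(as.character(set), names(set)))
  }
  if (inherits(x, "DNAStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x)) return(x)
  stop("unsupported sequence source")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
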