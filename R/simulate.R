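#' Generate a random genome, optionally sharing segments with donors
#'
#' Draws an i.i.d. uniform ACGT sequence. When \code{shared_segments} is
#' given, segments copied from donor genomes are pasted in at random
#' positions and point substitutions are applied so that the pasted copy
#' matches the donor at the requested identity -- this emulates communities
#' in which closely related strains co-exist and share homologous regions.
#'
#' @param length genome length in bases, > 0.
#' @param seed optional integer seed (deterministic output per seed).
#' @param shared_segments optional data frame with columns \code{donor}
#'   (name into \code{donors}), \code{length} (segment length) and
#'   \code{identity} (fraction in \[0, 1\]).
#' @param donors named character vector of donor genome sequences.
#' @return a single DNA string.
#' @export
make_genome <- function(length, seed = NULL, shared_segments = NULL,
                        donors = NULL) {
  stopifnot(length > 0)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  g <- sample(bases, length, replace = TRUE)
  if (!is.null(shared_segments)) {
    stopifnot(is.data.frame(shared_segments),
              all(c("donor", "length", "identity") %in%
                    names(shared_segments)),
              !is.null(donors))
    for (i in seq_len(nrow(shared_segments))) {
      dn <- shared_segments$donor[i]
      sl <- shared_segments$length[i]
      idy <- shared_segments$identity[i]
      if (idy < 0 || idy > 1) stop("identity must be in [0, 1]")
      donor <- donors[[dn]]
      if (is.null(donor) || nchar(donor) < sl)
        stop("donor '", dn, "' is missing or shorter than the segment")
      if (sl > length) stop("segment longer than the genome")
      from <- sample.int(nchar(donor) - sl + 1, 1)
      seg <- strsplit(substr(donor, from, from + sl - 1), "")[[1]]
      n_mut <- round((1 - idy) * sl)
      if (n_mut > 0) {
        pos <- sample.int(sl, n_mut)
        seg[pos] <- vapply(seg[pos],
                           function(b) sample(setdiff(bases, b), 1), "")
      }
      at <- sample.int(length - sl + 1, 1)
      g[at:(at + sl - 1)] <- seg
    }
  }
  paste(g, collapse = "")
}

#' Simulate shotgun reads from a community
#'
#' Uniform shotgun sampler: read start positions are uniform over
#' \code{[1, len - L + 1]}, strands are uniform, and substitution errors are
#' i.i.d. at rate \code{error_rate} (no indels -- the k-mer machinery is
#' exact, so substitutions are the relevant perturbation). Reads are sampled
#' with replacement. Two allocation modes:
#' \itemize{
#'   \item \strong{depth mode} (\code{depth} given): genome g contributes
#'     \code{round(depth_g * len_g / L)} reads;
#'   \item \strong{abundance mode} (\code{abundance} and \code{n_reads}
#'     given): the \code{n_reads} reads are allocated multinomially with
#'     weights \code{RA_g * len_g}, i.e. abundance is genome-copy (per-base
#'     coverage) proportion, so a fold change R in abundance is a fold change
#'     R in coverage.
#' }
#' Provenance is recorded in the read id as
#' \code{genomeID|start|strand|serial}.
#'
#' @param genomes named character vector of genome sequences.
#' @param abundance named numeric vector of relative abundances (> 0).
#' @param n_reads total number of reads (abundance mode).
#' @param depth named numeric vector of per-genome sequencing depths.
#' @param read_length read length L (default 100).
#' @param error_rate per-base substitution rate, in \[0, 0.5) (default 0.002,
#'   a post-quality-control short-read substitution rate).
#' @param paired simulate read pairs (fixed insert size); mates carry
#'   \code{/1} and \code{/2} id suffixes.
#' @param insert_size outer fragment length for paired mode (default 500).
#' @param seed optional integer seed.
#' @return a read-set data frame (\code{id}, \code{sequence}, \code{quality}
#'   = \code{NA}) with one row per read.
#' @export
simulate_sample <- function(genomes, abundance = NULL, n_reads = NULL,
                            depth = NULL, read_length = 100,
                            error_rate = 0.002, paired = FALSE,
                            insert_size = 500, seed = NULL) {
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(read_length)
  lens <- nchar(genomes)
  span <- if (paired) insert_size else L
  usable <- lens >= span
  if (!all(usable)) {
    warning("skipping genomes shorter than the sampled span: ",
            paste(names(genomes)[!usable], collapse = ", "))
    genomes <- genomes[usable]
    lens <- lens[usable]
  }
  if (length(genomes) == 0) stop("no genome is long enough")

  if (!is.null(depth)) {
    depth <- depth[names(genomes)]
    if (anyNA(depth)) stop("depth must name every usable genome")
    n_frag <- round(depth * lens / L)
    if (paired) n_frag <- round(n_frag / 2)
  } else {
    if (is.null(abundance) || is.null(n_reads))
      stop("give either depth, or abundance together with n_reads")
    abundance <- abundance[names(genomes)]
    if (anyNA(abundance) || any(abundance <= 0))
      stop("abundance must be positive for every usable genome")
    total <- if (paired) round(n_reads / 2) else n_reads
    w <- abundance * lens
    n_frag <- as.vector(rmultinom(1, total, w / sum(w)))
    names(n_frag) <- names(genomes)
  }

  parts <- lapply(names(genomes), function(gid) {
    n <- n_frag[[gid]]
    if (n < 1) return(NULL)
    gseq <- genomes[[gid]]
    glen <- lens[[gid]]
    if (paired) {
      fs <- sample.int(glen - insert_size + 1, n, replace = TRUE)
      fwd1 <- substring(gseq, fs, fs + L - 1L)
      end2 <- fs + insert_size - 1L
      fwd2 <- revcomp(substring(gseq, end2 - L + 1L, end2))
      flip <- runif(n) < 0.5 # which mate is /1
      r1 <- ifelse(flip, fwd2, fwd1)
      r2 <- ifelse(flip, fwd1, fwd2)
      s1 <- ifelse(flip, end2 - L + 1L, fs)
      s2 <- ifelse(flip, fs, end2 - L + 1L)
      d1 <- ifelse(flip, "-", "+")
      d2 <- ifelse(flip, "+", "-")
      data.frame(
        id = c(sprintf("%s|%d|%s|%07d/1", gid, s1, d1, seq_len(n)),
               sprintf("%s|%d|%s|%07d/2", gid, s2, d2, seq_len(n))),
        sequence = c(r1, r2), stringsAsFactors = FALSE)
    } else {
      starts <- sample.int(glen - L + 1L, n, replace = TRUE)
      seqs <- substring(gseq, starts, starts + L - 1L)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      rev <- strands == "-"
      if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
      data.frame(
        id = sprintf("%s|%d|%s|%07d", gid, starts, strands, seq_len(n)),
        sequence = seqs, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$sequence <- add_substitutions(out$sequence, error_rate)
  out$quality <- NA_character_
  out
}

add_substitutions <- function(seqs, e) {
  if (e <= 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), nchar(seqs), e)
  idx <- which(n_err > 0)
  for (i in idx) {
    s <- strsplit(seqs[[i]], "")[[1]]
    pos <- sample.int(length(s), n_err[[i]])
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), "")
    seqs[[i]] <- paste(s, collapse = "")
  }
  seqs
}

#' Parse provenance from simulated read ids
#'
#' Inverts the \code{genomeID|start|strand|serial} id convention of
#' \code{\link{simulate_sample}} (a trailing \code{/1}/\code{/2} mate suffix
#' is tolerated).
#'
#' @param ids character vector of read ids.
#' @return data frame with columns \code{id}, \code{genome}, \code{start},
#'   \code{strand}.
#' @export
parse_provenance <- function(ids) {
  core <- sub("/[12]$", "", ids)
  parts <- strsplit(core, "|", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("ids do not carry genomeID|start|strand provenance")
  data.frame(
    id = ids,
    genome = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    strand = vapply(parts, `[`, "", 3),
    stringsAsFactors = FALSE)
}

#' Community design of the five-genome fold-change simulation
#'
#' Relative abundances of five genomes across five samples; sample S1 holds
#' the focal genome (\code{S_thermophilus}) at a uniquely high abundance, and
#' its fold change relative to samples S2--S5 is 16, 8, 4 and 2. In every
#' sample exactly one non-focal genome is raised to 16 so that total
#' community size stays comparable.
#'
#' @return a 5 x 5 numeric matrix (genomes x samples S1--S5).
#' @export
fold_change_design <- function() {
  m <- rbind(
    F_acidarmanus  = c(16, 1, 1, 1, 1),
    L_gasseri      = c(2, 2, 16, 2, 2),
    P_pentosaceus  = c(4, 4, 4, 16, 4),
    P_marinus      = c(8, 8, 8, 8, 16),
    S_thermophilus = c(16, 1, 2, 4, 8))
  colnames(m) <- paste0("S", 1:5)
  m
}

#' Depth-series design and published reference values
#'
#' Five paired samples sharing the S1/S4 community structure of
#' \code{\link{fold_change_design}} (focal-genome fold change fixed at 4),
#' with the focal genome sequenced at 4--20x in S1 and 1--5x in S4. The
#' published reference columns are the expected percentage of bases with >= 2
#' times the coverage in S1 than in S4, the percentage of focal-genome reads
#' extracted at r = 2, and the fraction of the genome assembled from the
#' extracted reads.
#'
#' @return data frame with columns \code{depth_s1}, \code{depth_s4},
#'   \code{expected_diff_base_pct}, \code{extracted_reads_pct},
#'   \code{assembled_pct}.
#' @export
depth_series_benchmark <- function() {
  data.frame(
    depth_s1 = c(4, 8, 12, 16, 20),
    depth_s4 = c(1, 2, 3, 4, 5),
    expected_diff_base_pct = c(82.15, 86.96, 90.58, 92.96, 94.79),
    extracted_reads_pct = c(86.69, 88.93, 93.15, 95.53, 96.91),
    assembled_pct = c(31.72, 67.31, 83.72, 90.92, 93.82))
}

#' Strain-panel design of the related-strains simulation
#'
#' Five strains of one species in two samples: strain HaA2 dominates S1 and
#' CGA009 dominates S2, while three background strains stay at equal
#' abundance; sequencing depth is proportional to relative abundance (6x per
#' abundance unit). \code{genome_length} scales the strain genomes for desk
#' use (the natural genomes are ~5 Mb).
#'
#' @param genome_length scaled strain genome length (default 50000).
#' @return data frame with columns \code{strain}, \code{length},
#'   \code{ra_s1}, \code{ra_s2}, \code{depth_s1}, \code{depth_s2}.
#' @export
strain_panel_design <- function(genome_length = 50000) {
  ra1 <- c(3, 3, 3, 0.1, 5)
  ra2 <- c(3, 3, 3, 5, 0.1)
  data.frame(
    strain = c("BisA53", "BisB18", "BisB5", "CGA009", "HaA2"),
    length = genome_length,
    ra_s1 = ra1, ra_s2 = ra2,
    depth_s1 = 6 * ra1, depth_s2 = 6 * ra2,
    stringsAsFactors = FALSE)
}

#' Simulate a gene-by-sample mapped-read count matrix
#'
#' Synthetic input for the differential-gene stage: per-gene baseline
#' abundances (reads per billion) are log-normal across genes; per-sample
#' totals are uniform on \code{total_range}; counts are Poisson with mean
#' \code{abundance * total / 1e9}. Genes listed in \code{planted} have their
#' abundance multiplied by \code{fold} in group 1 only.
#'
#' @param n_genes number of genes.
#' @param n1,n2 samples per group.
#' @param planted indices of genes enriched in group 1 (default none).
#' @param fold abundance fold change of planted genes (default 10).
#' @param meanlog,sdlog log-normal baseline parameters (default log(200), 1).
#' @param total_range per-sample total-read range (default 2e7--4e7, typical
#'   gut shotgun datasets).
#' @param seed optional integer seed.
#' @return an \code{abundance_matrix} (see \code{\link{abundance_matrix}}).
#' @export
simulate_gene_counts <- function(n_genes, n1, n2, planted = integer(0),
                                 fold = 10, meanlog = log(200), sdlog = 1,
                                 total_range = c(2e7, 4e7), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_s <- n1 + n2
  totals <- round(runif(n_s, total_range[1], total_range[2]))
  base <- rlnorm(n_genes, meanlog, sdlog)
  lam <- outer(base, totals / 1e9)
  if (length(planted))
    lam[planted, seq_len(n1)] <- lam[planted, seq_len(n1)] * fold
  counts <- matrix(rpois(length(lam), lam), nrow = n_genes,
                   dimnames = list(paste0("gene", seq_len(n_genes)),
                                   paste0("sample", seq_len(n_s))))
  abundance_matrix(counts, totals,
                   rep(c("group1", "group2"), c(n1, n2)))
}
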