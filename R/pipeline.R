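#' Build a subtractive-assembly run configuration
#'
#' Validates and bundles the parameters of a two-group run. \code{ladder}
#' drives iterative extraction; set \code{r} instead for a single-pass run at
#' one ratio. An optional \code{assembler} command template with
#' \code{{reads}} and \code{{out}} placeholders is invoked per direction
#' after extraction.
#'
#' @param group_a,group_b file lists (FASTA/FASTQ, optionally gzipped) for
#'   the two pooled groups.
#' @param out_dir output directory (created if missing).
#' @param k k-mer length (default 25).
#' @param p distinctive-read fraction (default 0.5).
#' @param ladder threshold ladder (default \code{c("unique",10,8,6,4,2)}).
#' @param r single ratio threshold; overrides \code{ladder} when given.
#' @param fpr bloom false-positive target (default 0.01).
#' @param expected_kmers expected distinct k-mers per group (optional).
#' @param assembler optional external assembler command template.
#' @param seed integer seed recorded in the run log.
#' @return a \code{run_config} list.
#' @export
run_config <- function(group_a, group_b, out_dir, k = 25, p = 0.5,
                       ladder = c("unique", 10, 8, 6, 4, 2), r = NULL,
                       fpr = 0.01, expected_kmers = NULL, assembler = NULL,
                       seed = 1L) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  missing <- c(group_a, group_b)[!file.exists(c(group_a, group_b))]
  if (length(missing))
    stop("missing input files: ", paste(missing, collapse = ", "))
  if (k < 15 || k > 31) stop("k must be within [15, 31]")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (!is.null(r) && r < 1) stop("r must be >= 1")
  structure(list(group_a = group_a, group_b = group_b, out_dir = out_dir,
                 k = as.integer(k), p = p, ladder = as.character(ladder),
                 r = r, fpr = fpr, expected_kmers = expected_kmers,
                 assembler = assembler, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields matching \code{\link{run_config}}
#'   arguments.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the subtractive pipeline over two pooled groups
#'
#' Counts k-mers over the pooled reads of each group, then extracts
#' distinctive reads in both directions (A minus B and B minus A) --
#' iteratively over the configured ladder, or single-pass when \code{r} is
#' set. Per-direction strata are written as FASTA/FASTQ (plus one merged
#' file), together with count tables, a manifest TSV, and a run log
#' recording parameters and package version. If an assembler command
#' template is configured it is invoked on each direction's merged reads;
#' a nonzero exit is recorded and the extraction outputs are kept intact.
#'
#' @param config a \code{run_config}.
#' @return invisibly, a list with the manifest data frame, per-direction
#'   strata, count tables, and assembler results (if any).
#' @export
run_subtractive <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat(sprintf("subkmer %s\nstarted: %s\nseed: %d\nk: %d  p: %g  fpr: %g\n",
              as.character(utils::packageVersion("subkmer")),
              format(Sys.time()), config$seed, config$k, config$p,
              config$fpr),
      file = log_path)
  logf("thresholds: %s",
       if (is.null(config$r)) paste(config$ladder, collapse = ",")
       else paste0("r=", config$r))

  reads_a <- read_reads(config$group_a)
  reads_b <- read_reads(config$group_b)
  logf("group A: %d reads from %d file(s); group B: %d reads from %d file(s)",
       nrow(reads_a), length(config$group_a),
       nrow(reads_b), length(config$group_b))

  tab_a <- count_kmers(reads_a, k = config$k, fpr = config$fpr,
                       expected_kmers = config$expected_kmers)
  tab_b <- count_kmers(reads_b, k = config$k, fpr = config$fpr,
                       expected_kmers = config$expected_kmers)
  write_count_table(tab_a, file.path(config$out_dir, "group_a.kmers.tsv"))
  write_count_table(tab_b, file.path(config$out_dir, "group_b.kmers.tsv"))
  logf("counted: A %d k-mers / %.0f bases; B %d k-mers / %.0f bases",
       length(tab_a), tab_a$total_bases, length(tab_b), tab_b$total_bases)

  fastq <- !all(is.na(reads_a$quality))
  ext <- if (fastq) "fq" else "fa"
  directions <- list(
    A_minus_B = list(reads = reads_a, from = tab_a, against = tab_b),
    B_minus_A = list(reads = reads_b, from = tab_b, against = tab_a))

  strata_out <- list()
  assembler_out <- list()
  manifest <- NULL
  for (dir_name in names(directions)) {
    d <- directions[[dir_name]]
    if (is.null(config$r)) {
      strata <- iterative_extract(d$reads, d$from, d$against, p = config$p,
                                  ladder = config$ladder,
                                  direction = dir_name)
    } else {
      sig <- differential_kmers(d$from, d$against, config$r, dir_name)
      one <- extract_reads(d$reads, sig, p = config$p)
      strata <- structure(
        setNames(list(list(label = as.character(config$r),
                           direction = dir_name, reads = one)),
                 as.character(config$r)),
        class = "extraction_strata")
    }
    strata_out[[dir_name]] <- strata
    for (s in strata) {
      f <- file.path(config$out_dir,
                     sprintf("%s.r%s.%s", dir_name, s$label, ext))
      write_reads(s$reads, f)
    }
    merged <- strata_reads(strata)
    merged_path <- file.path(config$out_dir,
                             sprintf("%s.extracted.%s", dir_name, ext))
    write_reads(merged, merged_path)
    m <- strata_manifest(strata)
    manifest <- rbind(manifest, m)
    logf("%s: %d reads extracted over %d rung(s)", dir_name, nrow(merged),
         nrow(m))

    if (!is.null(config$assembler)) {
      out_prefix <- file.path(config$out_dir, paste0(dir_name, ".assembly"))
      cmd <- gsub("{reads}", merged_path, config$assembler, fixed = TRUE)
      cmd <- gsub("{out}", out_prefix, cmd, fixed = TRUE)
      status <- system(cmd)
      assembler_out[[dir_name]] <- list(command = cmd, status = status,
                                        out = out_prefix)
      if (status != 0) {
        logf("assembler FAILED (exit %d) for %s; extraction outputs kept",
             status, dir_name)
      } else {
        logf("assembler finished for %s -> %s", dir_name, out_prefix)
      }
    }
  }
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  logf("manifest written: %s", manifest_path)
  invisible(list(manifest = manifest, strata = strata_out,
                 tables = list(A = tab_a, B = tab_b),
                 assembler = assembler_out))
}
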