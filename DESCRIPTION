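Package: subkmer
Title: Subtractive Assembly Preprocessing for Comparative Metagenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies k-mers whose per-base-normalized frequency differs
    between two pooled groups of shotgun metagenomes using bloom-filter
    counting with singleton exclusion, extracts the reads carrying those
    differential signatures (single-pass at a fixed ratio threshold or
    iteratively over a ladder of thresholds), and hands the reduced read
    sets to any external metagenomic assembler. Includes a provenance-aware
    shotgun community simulator, extraction and assembly quality metrics
    (sensitivity, N50, anchor-based genome fraction, a Poisson model of
    differential base coverage), and downstream differential-gene statistics
    (reads-per-billion normalization, one-sided Wilcoxon rank-sum tests with
    Benjamini-Hochberg FDR control).
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
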