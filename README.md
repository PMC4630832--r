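# subkmer

Subtractive-assembly preprocessing for comparative metagenomics.

Given shotgun metagenomes in two condition groups (e.g. case vs control gut
microbiomes), most of the sequence is shared background that bloats and
tangles any direct assembly. `subkmer` isolates the *compositional
difference* before assembly: it counts canonical k-mers per pooled group
with a bloom filter (discarding error-dominated singletons), identifies
k-mers whose per-base-normalized frequency is at least `r`-fold higher in
one group,

&nbsp;&nbsp;&nbsp;&nbsp; keep k-mer *x* of A &nbsp;iff&nbsp; c_A(x)/L_A ≥ r · c_B(x)/L_B,

and extracts the *distinctive* reads — those in which at least a fraction
`p` (default 50 %) of k-mer windows are such signatures. When the true
degree of difference is unknown, extraction runs iteratively over a ladder
of thresholds (unique k-mers first, then ratios 10, 8, 6, 4, 2), producing
disjoint strata ordered by stringency. The reduced read sets go to any
external assembler. The guiding rule of thumb: a genome whose coverage
differs `R`-fold between groups is captured effectively at thresholds up to
`r = R/2`.

Companion modules provide a provenance-tagged community read simulator,
extraction/assembly quality metrics (sensitivity and precision from
provenance, N50 and cumulative contig curves, anchor-based genome fraction,
a Poisson model of differential base coverage), and the downstream
differential-gene stage (reads-per-billion normalization, one-sided
Wilcoxon rank-sum tests, Benjamini–Hochberg FDR, `q < 0.01` selection).

## Worked example

Two synthetic 20-kb genomes; one is 12-fold enriched in the case sample:

```r
library(subkmer)
genomes <- c(shared = make_genome(20000, seed = 1),
             case_only = make_genome(20000, seed = 2))
case <- simulate_sample(genomes, depth = c(shared = 10, case_only = 12), seed = 3)
ctrl <- simulate_sample(genomes, depth = c(shared = 10, case_only = 1),  seed = 4)

tab_case <- count_kmers(case, k = 25)
tab_ctrl <- count_kmers(ctrl, k = 25)
tab_case
#> kmer_count_table: k = 25, 39,777 k-mers (count >= 2), 440,000 bases in 4,400 reads

strata <- iterative_extract(case, tab_case, tab_ctrl)
strata_manifest(strata)
#>        direction threshold n_reads gigabases
#> unique A_minus_B    unique    2095 0.0002095
#> 10     A_minus_B        10       0 0.0000000
#> 8      A_minus_B         8       0 0.0000000
#> 6      A_minus_B         6       0 0.0000000
#> 4      A_minus_B         4       0 0.0000000
#> 2      A_minus_B         2     183 0.0000183

m <- extraction_metrics(strata_reads(strata)$id, parse_provenance(case$id),
                        "case_only")
sprintf("sensitivity %.4f  precision %.4f", m$sensitivity, m$precision)
#> [1] "sensitivity 0.9433  precision 0.9939"
```

Reading the output: the control sample carries the enriched genome at only
1×, so after singleton exclusion most of its k-mers are entirely absent
from the control table — the bulk of its reads land in the `unique`
stratum, a further 183 at ratio 2, and nothing in between (the contrast is
all-or-nothing at this depth). 94 % of the enriched genome's reads are
recovered at 99 % purity; the extracted files (plus a merged one) are what
an assembler would receive, e.g. via
`run_subtractive(run_config(..., assembler = "megahit -r {reads} -o {out}"))`.

The methods vignette (`vignettes/subtractive-assembly.Rmd`) documents the
model, every tunable parameter, what the simulator does and does not
emulate, and the numerical conventions (inclusive thresholds, N50, anchor
fraction, the Poisson coverage model).

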