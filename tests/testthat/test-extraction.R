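# Build a read with a known number of valid windows (V) of which a chosen
# subset is placed into the signature (D).
make_read_case <- function(k = 15, V = 10, seed = 1) {
  set.seed(seed)
  repeat {
    read <- paste(sample(c("A", "C", "G", "T"), V + k - 1, replace = TRUE),
                  collapse = "")
    wins <- canonical_chr(all_windows(read, k))
    if (anyDuplicated(wins) == 0) return(list(read = read, windows = wins))
  }
}

sig_of <- function(kmers, k = 15) {
  subkmer:::new_signature_set(kmers, k, "A_minus_B", 2)
}

test_that("distinctive-read rule: fraction p of valid windows, at least one hit", {
  case <- make_read_case(V = 10)
  expect_true(is_distinctive(case$read, sig_of(case$windows[1:5]), p = 0.5))
  expect_false(is_distinctive(case$read, sig_of(case$windows[1:4]), p = 0.5))
  # even p = 0 requires one signature window
  expect_false(is_distinctive(case$read, sig_of(random_kmers(5, 15)), p = 0))
  expect_true(is_distinctive(case$read, sig_of(case$windows[1]), p = 0))
  # reads shorter than k are never distinctive
  expect_false(is_distinctive("ACGT", sig_of(case$windows), p = 0))
  # ambiguous bases void windows: V counts only ACGT windows
  nread <- paste0(case$read, "N", "ACGTACGTACGTACG")
  expect_true(is_distinctive(nread, sig_of(case$windows[1:8]), p = 0.5))
})

test_that("raising p never adds reads", {
  set.seed(201)
  reads <- random_reads(50, c(40, 70))
  sig <- sig_of(unique(canonical_chr(unlist(
    lapply(reads[1:20], all_windows, k = 15)))))
  prev <- rep(TRUE, length(reads))
  for (p in c(0, 0.25, 0.5, 0.75, 1)) {
    cur <- is_distinctive(reads, sig, p)
    expect_true(all(cur <= prev), info = paste("p =", p))
    prev <- cur
  }
})

test_that("extract_reads returns qualifying reads in input order", {
  case1 <- make_read_case(V = 8, seed = 5)
  case2 <- make_read_case(V = 8, seed = 6)
  reads <- data.frame(id = c("a", "b"),
                      sequence = c(case1$read, case2$read),
                      stringsAsFactors = FALSE)
  # signature covers read 1 only
  out <- extract_reads(reads, sig_of(case1$windows), p = 0.5)
  expect_equal(out$id, "a")
  # empty signature extracts nothing
  expect_equal(nrow(extract_reads(reads, sig_of(character(0)), p = 0.5)), 0)
})

test_that("paired extraction pulls the mate of a distinctive read", {
  case <- make_read_case(V = 10, seed = 7)
  other <- make_read_case(V = 10, seed = 8)
  reads <- data.frame(
    id = c("frag1/1", "frag1/2", "frag2/1", "frag2/2"),
    sequence = c(case$read, other$read, other$read, other$read),
    stringsAsFactors = FALSE)
  sig <- sig_of(case$windows)
  expect_equal(extract_reads(reads, sig, pair_mode = "both")$id,
               c("frag1/1", "frag1/2"))
  expect_equal(extract_reads(reads, sig, pair_mode = "independent")$id,
               "frag1/1")
})

test_that("reads from an enriched genome are extracted, shared genome is not", {
  set.seed(211)
  gX <- make_genome(400, seed = 31) # 4x enriched in A
  gS <- make_genome(400, seed = 32) # shared equally
  mk <- function(g, n) vapply(seq_len(n), function(i) {
    s <- sample.int(nchar(g) - 59, 1)
    substr(g, s, s + 59)
  }, "")
  readsA <- c(mk(gX, 80), mk(gS, 80))
  readsB <- c(mk(gX, 20), mk(gS, 80))
  tA <- count_kmers(readsA, k = 15)
  tB <- count_kmers(readsB, k = 15)
  sig <- differential_kmers(tA, tB, 2)
  keep <- is_distinctive(readsA, sig, 0.5)
  # brute-force per-read membership oracle
  oracle <- vapply(readsA, function(rd) {
    wins <- canonical_chr(all_windows(rd, 15))
    sum(wins %in% sig$kmers) >= ceiling(0.5 * length(wins)) &&
      any(wins %in% sig$kmers)
  }, TRUE, USE.NAMES = FALSE)
  expect_equal(keep, oracle)
  expect_gt(mean(keep[1:80]), 0.8)     # enriched genome comes out
  expect_lt(mean(keep[81:160]), 0.2)   # shared genome stays
})

test_that("iterative strata are disjoint, ordered, and union to the r=2 pass", {
  set.seed(221)
  for (rep in 1:5) {
    genomes <- setNames(lapply(1:3, function(i) make_genome(600)), NULL)
    genomes <- c(g1 = genomes[[1]], g2 = genomes[[2]], g3 = genomes[[3]])
    rA <- simulate_sample(genomes, depth = c(g1 = 12, g2 = 6, g3 = 6),
                          read_length = 50, error_rate = 0)
    rB <- simulate_sample(genomes, depth = c(g1 = 1, g2 = 6, g3 = 3),
                          read_length = 50, error_rate = 0)
    tA <- count_kmers(rA, k = 15)
    tB <- count_kmers(rB, k = 15)
    strata <- iterative_extract(rA, tA, tB, p = 0.5)
    ids <- lapply(strata, function(s) s$reads$id)
    expect_equal(anyDuplicated(unlist(ids)), 0)
    single <- extract_reads(rA, differential_kmers(tA, tB, 2), p = 0.5,
                            pair_mode = "independent")
    expect_setequal(unlist(ids), single$id)
  }
})

test_that("stratum assignment lands on the first qualifying rung", {
  set.seed(231)
  ks <- unique(random_kmers(30, 15))
  case <- make_read_case(V = 12, seed = 41)
  wins <- case$windows
  # all windows at normalized ratio 9: fails 10, passes 8
  A <- manual_table(c(wins, ks), rep(c(18, 4), c(length(wins), length(ks))),
                    1e5)
  B <- manual_table(c(wins, ks), rep(c(2, 4), c(length(wins), length(ks))),
                    1e5)
  strata <- iterative_extract(
    data.frame(id = "r1", sequence = case$read, stringsAsFactors = FALSE),
    A, B, p = 0.5)
  expect_equal(strata[["8"]]$reads$id, "r1")
  expect_equal(nrow(strata[["unique"]]$reads), 0)
  expect_equal(nrow(strata[["10"]]$reads), 0)

  # a read all of whose k-mers are absent from B lands in "unique"
  case2 <- make_read_case(V = 12, seed = 42)
  A2 <- manual_table(c(case2$windows, ks),
                     rep(c(5, 4), c(length(case2$windows), length(ks))), 1e5)
  B2 <- manual_table(ks, rep(4, length(ks)), 1e5)
  strata2 <- iterative_extract(
    data.frame(id = "r2", sequence = case2$read, stringsAsFactors = FALSE),
    A2, B2, p = 0.5)
  expect_equal(strata2[["unique"]]$reads$id, "r2")

  expect_error(iterative_extract(data.frame(id = "x", sequence = case$read),
                                 A, B, ladder = c("unique", 2, 10)),
               "decreasing")
})

test_that("extraction is deterministic", {
  set.seed(241)
  g <- c(a = make_genome(800), b = make_genome(800))
  rA <- simulate_sample(g, depth = c(a = 10, b = 4), read_length = 50,
                        error_rate = 0, seed = 9)
  rB <- simulate_sample(g, depth = c(a = 2, b = 4), read_length = 50,
                        error_rate = 0, seed = 10)
  tA <- count_kmers(rA, k = 15)
  tB <- count_kmers(rB, k = 15)
  s1 <- iterative_extract(rA, tA, tB)
  s2 <- iterative_extract(rA, tA, tB)
  expect_identical(s1, s2)
})
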