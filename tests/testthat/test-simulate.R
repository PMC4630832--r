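test_that("genome generation is deterministic per seed", {
  expect_identical(make_genome(1000, seed = 3), make_genome(1000, seed = 3))
  expect_false(make_genome(1000, seed = 3) == make_genome(1000, seed = 4))
  expect_true(grepl("^[ACGT]+$", make_genome(500, seed = 3)))
})

test_that("shared segments land at the requested identity", {
  # a donor-sized segment pins down where the copy sits, so identity can be
  # measured directly against the donor
  donor <- make_genome(800, seed = 13)
  g1 <- make_genome(3000, seed = 14, donors = c(d = donor),
                    shared_segments = data.frame(donor = "d", length = 800,
                                                 identity = 1))
  expect_true(grepl(donor, g1, fixed = TRUE))

  donor2 <- make_genome(1000, seed = 16)
  g2 <- make_genome(1000, seed = 15, donors = c(d = donor2),
                    shared_segments = data.frame(donor = "d", length = 1000,
                                                 identity = 0.9))
  ident <- mean(strsplit(g2, "")[[1]] == strsplit(donor2, "")[[1]])
  expect_gte(ident, 0.87)
  expect_lte(ident, 0.93)

  expect_error(make_genome(100, donors = c(d = "ACGT"),
                           shared_segments = data.frame(donor = "d",
                                                        length = 50,
                                                        identity = 1)),
               "shorter")
})

test_that("depth mode yields depth * length / read_length reads", {
  g <- c(g1 = make_genome(10000, seed = 23))
  s <- simulate_sample(g, depth = c(g1 = 10), read_length = 100,
                       error_rate = 0, seed = 5)
  expect_equal(nrow(s), 1000)
  prov <- parse_provenance(s$id)
  expect_true(all(prov$start >= 1 & prov$start <= 10000 - 100 + 1))
})

test_that("error-free reads are exact substrings at their provenance", {
  g <- c(g1 = make_genome(4000, seed = 33))
  s <- simulate_sample(g, depth = c(g1 = 5), read_length = 80,
                       error_rate = 0, seed = 6)
  prov <- parse_provenance(s$id)
  src <- substring(g[["g1"]], prov$start, prov$start + 79)
  expected <- ifelse(prov$strand == "-", rc_chr(src), src)
  expect_equal(s$sequence, expected)
})

test_that("substitution errors appear at close to the nominal rate", {
  g <- c(g1 = make_genome(4000, seed = 43))
  s <- simulate_sample(g, depth = c(g1 = 20), read_length = 80,
                       error_rate = 0.05, seed = 7)
  prov <- parse_provenance(s$id)
  src <- substring(g[["g1"]], prov$start, prov$start + 79)
  expected <- ifelse(prov$strand == "-", rc_chr(src), src)
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, s$sequence, expected)
  rate <- sum(mm) / sum(nchar(s$sequence))
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("abundance mode allocates reads by abundance x length", {
  set.seed(53)
  g <- c(g1 = make_genome(2000), g2 = make_genome(2000))
  s <- simulate_sample(g, abundance = c(g1 = 4, g2 = 1), n_reads = 10000,
                       read_length = 50, error_rate = 0, seed = 8)
  n1 <- sum(parse_provenance(s$id)$genome == "g1")
  expect_lt(abs(n1 - 8000), 3 * sqrt(10000 * 0.8 * 0.2))
})

test_that("simulation is deterministic and provenance survives FASTQ", {
  g <- c(g1 = make_genome(1500, seed = 63), g2 = make_genome(1500, seed = 64))
  a <- simulate_sample(g, depth = c(g1 = 4, g2 = 4), seed = 9,
                       read_length = 70)
  b <- simulate_sample(g, depth = c(g1 = 4, g2 = 4), seed = 9,
                       read_length = 70)
  expect_identical(a, b)

  path <- withr::local_tempfile(fileext = ".fq.gz")
  write_reads(a, path)
  back <- read_reads(path)
  expect_equal(back$id, a$id)
  expect_equal(back$sequence, a$sequence)
  expect_equal(parse_provenance(back$id)$genome,
               parse_provenance(a$id)$genome)
})

test_that("per-base coverage converges to nominal depth", {
  g <- c(g1 = make_genome(100000, seed = 73))
  s <- simulate_sample(g, depth = c(g1 = 20), read_length = 100,
                       error_rate = 0, seed = 10)
  prov <- parse_provenance(s$id)
  len <- 100000
  delta <- integer(len + 1)
  tab_s <- table(prov$start)
  delta[as.integer(names(tab_s))] <- as.integer(tab_s)
  ends <- table(pmin(prov$start + 100, len + 1))
  delta[as.integer(names(ends))] <- delta[as.integer(names(ends))] -
    as.integer(ends)
  cov <- cumsum(delta[seq_len(len)])
  # interior of the genome (edges are undersampled by construction)
  interior <- cov[101:(len - 100)]
  expect_lt(abs(mean(interior) - 20) / 20, 0.05)
})

test_that("paired mode produces proper mates with shared fragment ids", {
  g <- c(g1 = make_genome(5000, seed = 83))
  s <- simulate_sample(g, depth = c(g1 = 10), read_length = 80,
                       paired = TRUE, insert_size = 300, error_rate = 0,
                       seed = 11)
  expect_equal(nrow(s) %% 2, 0)
  frag <- sub("/[12]$", "", s$id)
  expect_true(all(table(sub(".*\\|", "", frag)) == 2))
  prov <- parse_provenance(s$id)
  src <- substring(g[["g1"]], prov$start, prov$start + 79)
  expected <- ifelse(prov$strand == "-", rc_chr(src), src)
  expect_equal(s$sequence, expected)
})

test_that("too-short genomes are skipped with a warning", {
  g <- c(ok = make_genome(1000, seed = 93), tiny = make_genome(50, seed = 94))
  expect_warning(
    s <- simulate_sample(g, depth = c(ok = 5, tiny = 5), read_length = 100,
                         error_rate = 0, seed = 12),
    "skipping")
  expect_true(all(parse_provenance(s$id)$genome == "ok"))
})

test_that("study-design presets are internally consistent", {
  d <- fold_change_design()
  expect_equal(dim(d), c(5, 5))
  # focal genome fold changes relative to S1
  expect_equal(d["S_thermophilus", "S1"] / d["S_thermophilus", 2:5],
               c(S2 = 16, S3 = 8, S4 = 4, S5 = 2))
  b <- depth_series_benchmark()
  expect_equal(b$depth_s1 / b$depth_s4, rep(4, 5))
  sp <- strain_panel_design()
  expect_equal(sp$depth_s1, 6 * sp$ra_s1)
  expect_equal(sp$depth_s2, 6 * sp$ra_s2)
})
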