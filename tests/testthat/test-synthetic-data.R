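# Synthetic genome/read generator: determinism, noiseless identities,
# placement bookkeeping, and read-simulation contracts.

test_that("repeat units are deterministic, length-bounded, and validated", {
  u1 <- make_repeat_unit(20, gc_fraction = 0.5, seed = 1)
  u2 <- make_repeat_unit(20, gc_fraction = 0.5, seed = 1)
  expect_identical(u1, u2)
  expect_equal(nchar(u1), 20)
  expect_equal(nchar(make_repeat_unit(13, seed = 2)), 13)
  expect_equal(nchar(make_repeat_unit(57, seed = 2)), 57)
  expect_false(make_repeat_unit(20, seed = 1) == make_repeat_unit(20, seed = 2))
  expect_error(make_repeat_unit(4, seed = 1), "length")
  expect_error(make_repeat_unit(501, seed = 1), "length")
})

test_that("noiseless tandem expansion is exact concatenation", {
  u <- make_repeat_unit(20, seed = 3)
  fs <- family_spec("f", u, copies_germline = 10)
  arr <- expand_tandem_array(fs, 10, seed = 1)
  expect_identical(arr$sequence, strrep(u, 10))
  expect_equal(nrow(arr$units), 10)
  expect_true(all(arr$units$strand == "+"))
  expect_equal(arr$units$start, seq(0, 180, by = 20))
  one <- expand_tandem_array(fs, 1, seed = 1)
  expect_identical(one$sequence, u)
})

test_that("indel-disrupted array length stays inside the binomial envelope", {
  u <- make_repeat_unit(20, seed = 4)
  fs <- family_spec("f", u, copies_germline = 1000, indel_rate = 0.05)
  arr <- expand_tandem_array(fs, 1000, seed = 9)
  # each of the <= N indel junctions adds or removes 1-3 bp; N is
  # Binomial(1000, 0.05), bounded here at the 1e-9 quantiles
  nmax <- qbinom(1 - 1e-9, 1000, 0.05)
  expect_gte(nchar(arr$sequence), 20 * 1000 - 3 * nmax)
  expect_lte(nchar(arr$sequence), 20 * 1000 + 3 * nmax)
  expect_equal(nrow(arr$units), 1000)  # indels never change the copy count
})

test_that("inverted cassettes are emitted reverse-complemented with truth", {
  u <- make_repeat_unit(30, seed = 5)
  fs <- family_spec("f", u, copies_germline = 100,
                    inverted_cassette_prob = 0.5, cassette_size = 10)
  arr <- expand_tandem_array(fs, 100, seed = 2)
  expect_gt(nrow(arr$cassettes), 0)
  for (i in seq_len(nrow(arr$cassettes))) {
    block <- substr(arr$sequence, arr$cassettes$start[i] + 1, arr$cassettes$end[i])
    expect_identical(block, strrep(revcomp(u), 10))
  }
  inv_units <- arr$units[arr$units$strand == "-", , drop = FALSE]
  expect_equal(nrow(inv_units) %% 10, 0)
})

test_that("genome pair plants shared families in both genomes only", {
  u <- make_repeat_unit(25, seed = 6)
  shared <- family_spec("shared", u, copies_germline = 40, copies_somatic = 40)
  gp <- build_genome_pair(list(shared), backbone_length = 20000, seed = 1)
  expect_identical(gp$germline, gp$somatic)

  v <- make_repeat_unit(30, seed = 7)
  restricted <- family_spec("germ", v, copies_germline = 2000)
  gp2 <- build_genome_pair(list(restricted), backbone_length = 100000, seed = 1)
  expect_false(identical(gp2$germline, gp2$somatic))
  expect_equal(sum(nchar(gp2$germline)), sum(nchar(gp2$somatic)))
  # ~60 kb planted span, absent from soma
  span <- sum(gp2$truth$end - gp2$truth$start)
  expect_equal(span, 60000)
  expect_false(grepl(v, gp2$somatic[[1]], fixed = TRUE))
  expect_true(grepl(strrep(v, 2), gp2$germline[[1]], fixed = TRUE))
  expect_equal(gp2$truth$expected_score[1], log2(2000))
})

test_that("placements are distributed, in bounds and non-overlapping", {
  fams <- list(
    family_spec("a", make_repeat_unit(20, seed = 8), 400, 400),
    family_spec("b", make_repeat_unit(31, seed = 9), 300))
  gp <- build_genome_pair(fams, backbone_length = 60000, n_sequences = 2,
                          seed = 3)
  truth <- gp$truth
  expect_setequal(unique(truth$seq_id), c("seq1", "seq2"))
  for (sid in unique(truth$seq_id)) {
    rows <- truth[truth$seq_id == sid, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    expect_true(all(rows$start >= 0))
    expect_true(all(rows$end <= nchar(gp$germline[[sid]])))
    if (nrow(rows) > 1)
      expect_true(all(rows$start[-1] >= rows$end[-nrow(rows)]))
  }
  # every planted array is literally present at its recorded coordinates
  for (i in seq_len(nrow(truth))) {
    seg <- substr(gp$germline[[truth$seq_id[i]]], truth$start[i] + 1, truth$end[i])
    expect_equal(nchar(seg), truth$end[i] - truth$start[i])
  }
  expect_error(
    build_genome_pair(list(family_spec("x", make_repeat_unit(20, seed = 1), 10000)),
                      backbone_length = 50000, seed = 1),
    "exceeds")
})

test_that("read simulation: exact yield, noiseless substrings, determinism", {
  genome <- c(chr = rdna(100000, seed = 10))
  cfg <- read_sim_config(read_length = 100, mean_coverage = 40,
                         error_rate = 0, paired = FALSE, seed = 5)
  p1 <- simulate_reads(genome, cfg, tempfile())
  expect_equal(attr(p1, "n_reads"), 40000)  # 40x * 100 kb / 100 bp
  reads <- germsat:::read_fastq_seqs(p1)
  expect_length(reads, 40000)
  pick <- reads[seq(1, 40000, length.out = 50)]
  fwd <- vapply(pick, grepl, TRUE, x = genome[[1]], fixed = TRUE)
  rev <- vapply(revcomp(pick), grepl, TRUE, x = genome[[1]], fixed = TRUE)
  expect_true(all(fwd | rev))
  p2 <- simulate_reads(genome, cfg, tempfile())
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_error(simulate_reads(c(s = rdna(50, seed = 1)), cfg, tempfile()),
               "read_length")
})

test_that("paired mode writes both mates at the configured insert scale", {
  genome <- c(chr = rdna(50000, seed = 11))
  cfg <- read_sim_config(read_length = 100, mean_coverage = 10,
                         error_rate = 0, paired = TRUE,
                         insert_mean = 300, insert_sd = 20, seed = 6)
  p <- simulate_reads(genome, cfg, tempfile())
  expect_length(p, 2)
  r1 <- germsat:::read_fastq_seqs(p[1])
  r2 <- germsat:::read_fastq_seqs(p[2])
  expect_equal(length(r1), length(r2))
  expect_equal(length(r1) + length(r2), attr(p, "n_reads"))
  # mates come from opposite strands of one fragment: R2 revcomp must also
  # be a genome substring
  pick <- seq(1, length(r2), length.out = 25)
  ok <- vapply(pick, function(i) {
    grepl(r2[i], genome[[1]], fixed = TRUE) ||
      grepl(revcomp(r2[i]), genome[[1]], fixed = TRUE)
  }, TRUE)
  expect_true(all(ok))
})

test_that("noiseless coverage round-trips within 5% of the target", {
  genome <- c(chr = rdna(10000, seed = 12))
  cfg <- read_sim_config(read_length = 100, mean_coverage = 40,
                         error_rate = 0, paired = FALSE, seed = 7)
  p <- simulate_reads(genome, cfg, tempfile())
  cov <- compute_coverage(p, genome)
  expect_equal(cov$unplaced, 0)
  expect_lt(abs(mean(cov$depth$chr) - 40) / 40, 0.05)
})

test_that("restricted-family k-mers occur only in germline reads", {
  u <- make_repeat_unit(40, seed = 13)
  fams <- list(
    family_spec("shared", make_repeat_unit(35, seed = 14), 100, 100),
    family_spec("germ", u, copies_germline = 200))
  gp <- build_genome_pair(fams, backbone_length = 40000, seed = 4)
  cfg <- read_sim_config(read_length = 100, mean_coverage = 15,
                         error_rate = 0, paired = FALSE, seed = 8)
  pg <- simulate_reads(gp$germline, cfg, tempfile())
  ps <- simulate_reads(gp$somatic, cfg, tempfile())
  unit_kmers <- unique(canonical_kmer(seq_windows(strrep(u, 2), 31)))
  kg <- spectrum_kmer_counts(count_kmers(pg, 31))
  ks <- spectrum_kmer_counts(count_kmers(ps, 31))
  expect_gt(length(intersect(unit_kmers, kg$kmer)), 0)
  expect_length(intersect(unit_kmers, ks$kmer), 0)
})

test_that("truth tables survive a TSV round trip", {
  fams <- list(family_spec("f", make_repeat_unit(22, seed = 15), 50, 50))
  gp <- build_genome_pair(fams, backbone_length = 10000, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_truth(gp$truth, path)
  back <- read_truth(path)
  expect_equal(back$family_id, gp$truth$family_id)
  expect_equal(back$start, gp$truth$start)
  expect_equal(back$expected_score, gp$truth$expected_score)
  expect_equal(truth_family_summary(back)$span_germline,
               truth_family_summary(gp$truth)$span_germline)
})
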