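# Canonical k-mer spectra: window/canonicalization semantics, brute-force
# oracle equivalence, histogram bookkeeping, modal copy number and the
# 3x-modal abundance threshold.

test_that("windows canonicalize as the lexicographic minimum", {
  sp <- count_kmers("ACGTA", k = 3)
  tab <- spectrum_kmer_counts(sp)
  # windows ACG, CGT, GTA; CGT canonicalizes to ACG; GTA (< TAC) stays
  expect_identical(tab$kmer, c("ACG", "GTA"))
  expect_identical(tab$count, c(2, 1))
})

test_that("empty and sub-k inputs give empty spectra", {
  expect_equal(nrow(spectrum_kmer_counts(count_kmers(character(0), 31))), 0)
  expect_equal(nrow(spectrum_kmer_counts(count_kmers("ACGTACGT", 31))), 0)
  # non-ACGT bases break the window
  tab <- spectrum_kmer_counts(count_kmers("ACGNACG", k = 3))
  expect_identical(tab$kmer, "ACG")
  expect_identical(tab$count, 2)
})

test_that("counting matches a brute-force dictionary scan", {
  seqs <- withr::with_seed(21, replicate(30, rdna(400)))
  for (k in c(7L, 31L)) {
    mine <- spectrum_kmer_counts(count_kmers(seqs, k))
    oracle <- brute_kmer_counts(seqs, k)
    expect_identical(mine$kmer, oracle$kmer)
    expect_identical(mine$count, oracle$count)
  }
})

test_that("spectra are closed under reverse complement of the reads", {
  seqs <- withr::with_seed(22, replicate(10, rdna(300)))
  a <- spectrum_kmer_counts(count_kmers(seqs, 15))
  b <- spectrum_kmer_counts(count_kmers(revcomp(seqs), 15))
  expect_identical(a, b)
})

test_that("histogram mass equals the number of counted instances", {
  seqs <- withr::with_seed(23, replicate(5, rdna(500)))
  sp <- count_kmers(c(seqs, seqs[1:2]), 21)
  h <- sp$histogram
  expect_equal(sum(h$count * h$n_kmers), sp$total_instances)
  expect_equal(sum(h$n_kmers), sp$n_distinct)
})

test_that("modal copy number follows the argmax rule with ties upward", {
  mers <- withr::with_seed(24, unique(replicate(40, rdna(5))))
  mers <- canonical_kmer(mers)
  mers <- unique(mers)[1:14]
  counts <- c(rep(1, 6), rep(2, 3), rep(55, 2), rep(56, 2), 70)
  sp <- spectrum_from_counts(mers, counts)
  # error peak (counts < 5) excluded; 55 and 56 both have 2 k-mers -> 56
  expect_equal(modal_copy_number(sp, error_peak_min = 5), 56)
  # single qualifying class
  sp2 <- spectrum_from_counts(mers[1:3], c(7, 7, 7))
  expect_equal(modal_copy_number(sp2), 7)
  # everything below the error-peak floor is an estimation error
  sp3 <- spectrum_from_counts(mers[1:3], c(1, 2, 3))
  expect_error(modal_copy_number(sp3), "modal")
})

test_that("abundance threshold is 3x the mode (inclusive comparison)", {
  mers <- canonical_kmer(unique(withr::with_seed(25, replicate(60, rdna(7)))))
  mers <- mers[!duplicated(mers)][1:12]
  counts <- c(rep(55, 6), 164, 165, 166, 300, 10, 20)
  sp <- spectrum_from_counts(mers, counts)
  expect_equal(modal_copy_number(sp), 55)
  expect_equal(abundance_threshold(sp, multiplier = 3), 165)
  ab <- abundant_kmers(sp, multiplier = 3)
  expect_equal(attr(ab, "threshold"), 165)
  expect_setequal(ab, mers[counts >= 165])  # 165 itself is kept
  # a mode of 60 gives the study's other printed threshold
  sp2 <- spectrum_from_counts(mers[1:4], c(60, 60, 60, 500))
  expect_equal(abundance_threshold(sp2), 180)
  # all counts below threshold -> empty set
  sp3 <- spectrum_from_counts(mers[1:3], c(10, 10, 11))
  expect_length(abundant_kmers(sp3, multiplier = 3), 0)
})

test_that("spectra persist to TSV + JSON and reload identically", {
  seqs <- withr::with_seed(26, replicate(4, rdna(200)))
  sp <- count_kmers(seqs, 11)
  path <- tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_spectrum(path)
  expect_identical(spectrum_kmer_counts(back), spectrum_kmer_counts(sp))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$k, 11)
})
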