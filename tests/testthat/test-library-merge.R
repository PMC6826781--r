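# Reference merge and known-repeat exclusion: replacement rules, thresholds,
# idempotence, exclusion counting against a pairwise oracle.

make_ref_containing <- function(core, total = 600, seed = 1) {
  withr::with_seed(seed, paste0(rdna(floor((total - nchar(core)) / 2)), core,
                                rdna(ceiling((total - nchar(core)) / 2))))
}

test_that("qualifying de novo sequences are replaced by the longer reference", {
  core <- rdna(200, seed = 61)
  denovo <- tiny_library(c(mutate_seq(core, 0.05, seed = 62)), prefix = "dn")
  reference <- data.frame(id = "ref1",
                          sequence = make_ref_containing(core, 600, seed = 63),
                          stringsAsFactors = FALSE)
  out <- merge_with_reference(denovo, reference)
  expect_true("ref1" %in% out$id)
  expect_false("dn01" %in% out$id)
  expect_equal(attr(out, "replaced")$denovo_id, "dn01")
  expect_equal(attr(out, "replaced")$reference_id, "ref1")
})

test_that("sub-threshold identity or coverage leaves the de novo sequence", {
  core <- rdna(200, seed = 64)
  reference <- data.frame(id = "ref1",
                          sequence = make_ref_containing(core, 600, seed = 65),
                          stringsAsFactors = FALSE)
  # 15% divergence: identity ~0.85 < 0.90
  low_id <- tiny_library(mutate_seq(core, 0.15, seed = 66), prefix = "dn")
  out1 <- merge_with_reference(low_id, reference)
  expect_true("dn01" %in% out1$id)
  # high identity but only half the de novo sequence aligns
  half <- tiny_library(paste0(core, rdna(220, seed = 67)), prefix = "dn")
  out2 <- merge_with_reference(half, reference)
  expect_true("dn01" %in% out2$id)
})

test_that("an empty or NULL reference is the identity merge", {
  denovo <- tiny_library(c(rdna(150, seed = 68), rdna(120, seed = 69)))
  expect_identical(merge_with_reference(denovo, NULL)$id, denovo$id)
  empty_ref <- data.frame(id = character(0), sequence = character(0))
  expect_identical(merge_with_reference(denovo, empty_ref)$id, denovo$id)
})

test_that("merging is idempotent and rejects duplicate ids", {
  core <- rdna(150, seed = 70)
  denovo <- tiny_library(c(mutate_seq(core, 0.03, seed = 71),
                           rdna(140, seed = 72)), prefix = "dn")
  reference <- data.frame(id = "ref1",
                          sequence = make_ref_containing(core, 500, seed = 73),
                          stringsAsFactors = FALSE)
  once <- merge_with_reference(denovo, reference)
  twice <- merge_with_reference(
    once[once$provenance == "denovo", , drop = FALSE], reference)
  expect_setequal(twice$id, once$id)
  dup <- denovo
  dup$id[1] <- "ref1"
  expect_error(merge_with_reference(dup, reference), "duplicate")
})

test_that("known-repeat exclusion removes matches at 99% and appends known once", {
  known_seq <- rdna(300, seed = 74)
  known <- data.frame(id = "germ1", sequence = known_seq,
                      stringsAsFactors = FALSE)
  lib <- tiny_library(c(known_seq,                      # exact copy
                        mutate_seq(known_seq, 0.05, seed = 75),  # 95%: keep
                        rdna(280, seed = 76)))
  out <- exclude_known(lib, known)
  expect_false("s01" %in% out$id)
  expect_true(all(c("s02", "s03", "germ1") %in% out$id))
  expect_equal(sum(out$id == "germ1"), 1)
  expect_equal(attr(out, "excluded"), "s01")
  # NULL known set is the identity
  expect_identical(exclude_known(lib, NULL)$id, lib$id)
})

test_that("exactly the planted near-copies of the known repeat are excluded", {
  known_seq <- rdna(400, seed = 77)
  known <- data.frame(id = "germ1", sequence = known_seq,
                      stringsAsFactors = FALSE)
  near <- vapply(1:3, function(i) mutate_seq(known_seq, 0.005, seed = 80 + i), "")
  far <- vapply(1:4, function(i) rdna(350, seed = 90 + i), "")
  # oracle check on the construction: near copies are >= 99% identical,
  # unrelated sequences share no long high-identity alignment
  for (s in near) {
    pa <- Biostrings::pairwiseAlignment(
      s, known_seq, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
      gapOpening = 5, gapExtension = 2)
    expect_gte(Biostrings::pid(pa, "PID1"), 99)
  }
  lib <- tiny_library(c(near, far))
  out <- exclude_known(lib, known)
  expect_setequal(attr(out, "excluded"), c("s01", "s02", "s03"))
  expect_equal(nrow(out), 4 + 1)
})

test_that("no two output sequences remain mutually near-identical after exclusion", {
  base <- rdna(300, seed = 95)
  lib <- tiny_library(c(base, mutate_seq(base, 0.002, seed = 96),
                        rdna(250, seed = 97)))
  known <- data.frame(id = "k1", sequence = base, stringsAsFactors = FALSE)
  out <- exclude_known(lib, known)
  ap <- align_pairs(out$sequence, out$sequence, min_cols = 50)
  ap <- ap[ap$query != ap$subject, , drop = FALSE]
  full <- ap[ap$aligned_query_fraction > 0.9, , drop = FALSE]
  expect_true(all(full$best_identity_min_cols < 0.99))
})
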