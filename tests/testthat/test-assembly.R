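# De Bruijn graph construction and unitig compaction: chain identities,
# branch handling, tandem cycles, determinism.

test_that("a single k-mer yields its window chain and reconstructs itself", {
  km <- rdna(31, seed = 31)
  g <- build_graph(km, 29)
  expect_equal(length(g$nodes), 3)
  expect_equal(nrow(graph_edges(g)), 2)
  lib <- assemble_unitigs(g, min_length = 29)
  expect_equal(nrow(lib), 1)
  expect_true(lib$sequence %in% c(km, revcomp(km)))
  expect_false(lib$is_cyclic)
  expect_equal(lib$member_kmer_count, 3)
})

test_that("overlapping k-mers chain into one path", {
  s <- rdna(32, seed = 32)
  kms <- c(substr(s, 1, 31), substr(s, 2, 32))  # overlap 30
  g <- build_graph(kms, 29)
  expect_equal(length(g$nodes), 4)
  lib <- assemble_unitigs(g, min_length = 29)
  expect_equal(nrow(lib), 1)
  expect_true(lib$sequence %in% c(s, revcomp(s)))
})

test_that("assembly is lossless on noiseless linear sequences", {
  for (seed in 33:35) {
    s <- rdna(300, seed = seed)
    kms <- seq_windows(s, 31)
    lib <- assemble_repeats(kms, min_length = 58)
    expect_equal(nrow(lib), 1)
    expect_true(lib$sequence %in% c(s, revcomp(s)))
    # input order and strand must not matter
    lib2 <- assemble_repeats(sample(canonical_kmer(kms)), min_length = 58)
    expect_identical(lib2$sequence, lib$sequence)
  }
})

test_that("a tandem unit forms a cycle linearized once with wraparound", {
  u <- rdna(40, seed = 36)
  kms <- unique(seq_windows(paste0(u, u), 31))[1:40]  # all rotations
  g <- build_graph(kms, 29)
  expect_equal(length(g$nodes), 40)
  lib <- assemble_unitigs(g)
  expect_equal(nrow(lib), 1)
  expect_true(lib$is_cyclic)
  expect_equal(lib$unit_length, 40)
  expect_equal(nchar(lib$sequence), 40 + 28)
  dbl <- paste0(lib$sequence, lib$sequence)
  expect_true(grepl(u, dbl, fixed = TRUE) || grepl(revcomp(u), dbl, fixed = TRUE))
})

test_that("cycle linearization is rotation- and strand-invariant", {
  u <- rdna(45, seed = 37)
  base <- assemble_repeats(unique(seq_windows(paste0(u, u), 31)))
  rot <- paste0(substr(u, 11, 45), substr(u, 1, 10))
  lib_rot <- assemble_repeats(unique(seq_windows(paste0(rot, rot), 31)))
  lib_rc <- assemble_repeats(unique(seq_windows(revcomp(paste0(u, u)), 31)))
  expect_identical(lib_rot$sequence, base$sequence)
  expect_identical(lib_rc$sequence, base$sequence)
})

test_that("branches cut paths and the branch prefix is shared", {
  p <- rdna(40, seed = 38)
  a <- rdna(40, seed = 39)
  b <- rdna(40, seed = 40)
  kms <- unique(c(seq_windows(paste0(p, a), 31), seq_windows(paste0(p, b), 31)))
  lib <- assemble_repeats(kms, min_length = 29)
  expect_gte(nrow(lib), 2)
  # the two full sequences are reconstructable from the pieces: each contig
  # is a substring of one of them
  ref <- c(paste0(p, a), paste0(p, b))
  ref <- c(ref, revcomp(ref))
  ok <- vapply(lib$sequence, function(s) any(vapply(ref, grepl, TRUE, x = s,
                                                    fixed = TRUE) |
                                               vapply(ref, function(r)
                                                 grepl(s, r, fixed = TRUE), TRUE)),
               TRUE)
  expect_true(all(ok))
  # the branch node (last 29 bp of the shared prefix) is shared by the
  # unitigs meeting at the branch
  bnode <- substr(p, 12, 40)
  carriers <- sum(vapply(lib$sequence, function(s)
    grepl(bnode, s, fixed = TRUE) || grepl(revcomp(bnode), s, fixed = TRUE),
    TRUE))
  expect_gte(carriers, 2)
})

test_that("short linear outputs are dropped and logged; cyclic are kept", {
  u <- rdna(13, seed = 41)
  cyc <- unique(seq_windows(paste0(strrep(u, 4)), 31))[1:13]
  short <- rdna(31, seed = 42)
  lib <- assemble_repeats(c(cyc, short), min_length = 58)
  expect_true(any(lib$is_cyclic))
  expect_false(short %in% lib$sequence || revcomp(short) %in% lib$sequence)
  dropped <- attr(lib, "dropped")
  expect_true(nrow(dropped) >= 1)
  lib2 <- assemble_repeats(c(cyc, short), min_length = 29)
  expect_true(short %in% lib2$sequence || revcomp(short) %in% lib2$sequence)
})

test_that("output ordering is deterministic: length descending, then sequence", {
  set.seed(43)
  kms <- unlist(lapply(c(120, 90, 90), function(n) seq_windows(rdna(n), 31)))
  lib <- assemble_repeats(kms, min_length = 58)
  lens <- nchar(lib$sequence)
  expect_true(all(diff(lens) <= 0))
  same <- which(duplicated(lens) | duplicated(lens, fromLast = TRUE))
  if (length(same) > 1)
    expect_true(all(diff(order(lens[same], lib$sequence[same])) > 0) ||
                  !is.unsorted(lib$sequence[same][order(-lens[same])]))
  lib2 <- assemble_repeats(sample(kms), min_length = 58)
  expect_identical(lib$sequence, lib2$sequence)
  expect_identical(lib$id, lib2$id)
})

test_that("empty input yields an empty graph and library, not an error", {
  g <- build_graph(character(0), 29)
  expect_equal(length(g$nodes), 0)
  expect_equal(nrow(assemble_unitigs(g)), 0)
})
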