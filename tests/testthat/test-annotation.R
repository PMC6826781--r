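# Tandem architecture annotation: core period detection, inverted cassettes,
# scaffold assignment, somatic ranking.

test_that("a perfect tandem array reports its unit with score 1", {
  u <- rdna(20, seed = 131)
  ann <- detect_core_unit(strrep(u, 10))
  expect_equal(ann$core_unit_length, 20)
  expect_equal(ann$periodicity_score, 1)
  # the consensus is a rotation-free copy of the unit
  expect_identical(ann$core_consensus, u)
})

test_that("period detection survives 3% substitutions and matches brute force", {
  u <- rdna(37, seed = 132)
  arr <- mutate_seq(strrep(u, 12), 0.03, seed = 133)
  ann <- detect_core_unit(arr, period_range = c(5, 200), min_score = 0.8)
  expect_equal(ann$core_unit_length, 37)
  expect_gte(ann$periodicity_score, 0.9)
  # independent brute-force score curve
  n <- nchar(arr)
  ch <- strsplit(arr, "")[[1]]
  brute <- vapply(5:200, function(p) {
    if (2 * p > n) return(NA_real_)
    mean(ch[1:(n - p)] == ch[(p + 1):n])
  }, 0)
  curve <- ann$score_curve
  keep <- !is.na(brute)
  expect_equal(curve$score[match(which(keep) + 4, curve$period)], brute[keep])
})

test_that("random sequence has no qualifying period", {
  r <- rdna(1000, seed = 134)
  ann <- detect_core_unit(r, min_score = 0.8)
  expect_true(is.na(ann$core_unit_length))
  expect_lt(ann$periodicity_score, 0.5)
  expect_error(detect_core_unit("ACGTACG", period_range = c(5, 200)), "short")
})

test_that("period detection is rotation invariant", {
  u <- rdna(31, seed = 135)
  arr <- strrep(u, 8)
  for (r in c(1, 7, 19)) {
    rot <- paste0(substr(arr, r + 1, nchar(arr)), substr(arr, 1, r))
    expect_equal(detect_core_unit(rot)$core_unit_length, 31)
  }
})

test_that("a constructed palindrome yields one cassette pair covering both arms", {
  S <- rdna(300, seed = 136)
  ic <- find_inverted_cassettes(paste0(S, revcomp(S)))
  expect_equal(nrow(ic), 1)
  expect_equal(ic$left_start, 0)
  expect_equal(ic$left_end, 300)
  expect_equal(ic$right_start, 300)
  expect_equal(ic$right_end, 600)
  expect_equal(ic$identity, 1)
})

test_that("pure forward tandem arrays contain no inverted cassettes", {
  u <- rdna(24, seed = 137)
  expect_equal(nrow(find_inverted_cassettes(strrep(u, 30))), 0)
})

test_that("planted inverted cassettes are recovered near their true bounds", {
  u <- make_repeat_unit(30, seed = 138)
  fs <- family_spec("f", u, copies_germline = 120,
                    inverted_cassette_prob = 0.2, cassette_size = 10)
  arr <- expand_tandem_array(fs, 120, seed = 139)
  truth <- arr$cassettes
  expect_gt(nrow(truth), 0)
  # adjacent inverted cassettes are seamless and merge into one block;
  # collapse touching truth intervals before comparing
  truth <- truth[order(truth$start), , drop = FALSE]
  merged <- list(c(truth$start[1], truth$end[1]))
  for (i in seq_len(nrow(truth))[-1]) {
    last <- merged[[length(merged)]]
    if (truth$start[i] == last[2]) {
      merged[[length(merged)]][2] <- truth$end[i]
    } else {
      merged[[length(merged) + 1]] <- c(truth$start[i], truth$end[i])
    }
  }
  ic <- find_inverted_cassettes(arr$sequence, min_cassette = 150)
  expect_gt(nrow(ic), 0)
  recovered <- vapply(merged, function(b) {
    any((abs(ic$left_start - b[1]) <= 10 & abs(ic$left_end - b[2]) <= 10) |
          (abs(ic$right_start - b[1]) <= 10 & abs(ic$right_end - b[2]) <= 10))
  }, TRUE)
  expect_true(all(recovered))
})

test_that("cassette detection mirrors under reverse complement of the input", {
  S <- rdna(250, seed = 140)
  spacer <- rdna(400, seed = 141)
  x <- paste0(S, spacer, revcomp(S))
  ic <- find_inverted_cassettes(x, min_cassette = 200)
  ic_rc <- find_inverted_cassettes(revcomp(x), min_cassette = 200)
  expect_equal(nrow(ic), nrow(ic_rc))
  n <- nchar(x)
  expect_setequal(n - ic$right_end, ic_rc$left_start)
  expect_setequal(n - ic$left_start, ic_rc$right_end)
})

test_that("scaffold assignment counts qualifying hits and picks the argmax", {
  rep_seq <- rdna(200, seed = 142)
  mk_scaffold <- function(n_copies, seed) {
    withr::with_seed(seed, paste(c(rbind(replicate(n_copies, rdna(500)),
                                         rep(rep_seq, n_copies)), rdna(400)),
                                 collapse = ""))
  }
  scaffolds <- c(A = mk_scaffold(5, 143), B = mk_scaffold(2, 144))
  asg <- assign_scaffold(rep_seq, scaffolds)
  expect_equal(asg$scaffold_id, "A")
  expect_equal(asg$hit_count, 5)
  expect_gte(asg$fraction_bases_aligned, 0.8)
  # input order must not matter
  asg2 <- assign_scaffold(rep_seq, rev(scaffolds))
  expect_equal(asg2$scaffold_id, "A")
  expect_equal(asg2$hit_count, 5)
  # absent repeat -> unassigned
  none <- assign_scaffold(rdna(200, seed = 145), scaffolds)
  expect_true(is.na(none$scaffold_id))
  expect_equal(none$hit_count, 0)
})

test_that("somatic ranking orders repeats by mean depth with ties by id", {
  lib <- tiny_library(c(rdna(100, seed = 146), rdna(100, seed = 147),
                        rdna(100, seed = 148)))
  depth <- list(s01 = rep(500L, 100), s02 = rep(5L, 100), s03 = rep(500L, 100))
  top <- rank_by_somatic_coverage(lib, depth, top_n = 2)
  expect_equal(top$id, c("s01", "s03"))  # tie at 500 broken by id
  expect_equal(top$mean_somatic_depth, c(500, 500))
  top1 <- rank_by_somatic_coverage(lib, depth, top_n = 1)
  expect_equal(top1$id, "s01")
})
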