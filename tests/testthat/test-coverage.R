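# Coverage, interval scanning, enrichment scoring, span estimation and the
# germline filter.

test_that("a single noiseless read deposits depth 1 over exactly its span", {
  ref <- c(target = rdna(1000, seed = 101))
  read <- substr(ref[[1]], 301, 400)
  cov <- compute_coverage(read, ref)
  expect_equal(cov$placed, 1)
  expect_equal(sum(cov$depth$target), 100)
  expect_equal(which(cov$depth$target == 1L), 301:400)
  # reverse-complemented read lands identically
  cov2 <- compute_coverage(revcomp(read), ref)
  expect_equal(cov2$depth$target, cov$depth$target)
})

test_that("reads sharing no seed with the reference are counted unplaced", {
  ref <- c(target = rdna(500, seed = 102))
  alien <- rdna(100, seed = 103)
  cov <- compute_coverage(alien, ref)
  expect_equal(cov$placed, 0)
  expect_equal(cov$unplaced, 1)
  expect_equal(sum(cov$depth$target), 0)
})

test_that("short tandem references are tiled for mapping", {
  u <- rdna(20, seed = 104)
  lib <- data.frame(id = c("sat", "plain"),
                    sequence = c(strrep(u, 3), rdna(400, seed = 105)),
                    provenance = "denovo", is_cyclic = c(FALSE, FALSE),
                    unit_length = NA_integer_, stringsAsFactors = FALSE)
  mr <- prepare_mapping_reference(lib, read_length = 100)
  expect_true(mr$tiled[mr$id == "sat"])
  expect_equal(mr$unit_length[mr$id == "sat"], 20)
  expect_gte(mr$map_length[mr$id == "sat"], 200)
  expect_false(mr$tiled[mr$id == "plain"])
  expect_equal(mr$map_length[mr$id == "plain"], 400)
  # cyclic consensi use their recorded period
  lib2 <- data.frame(id = "cyc", sequence = paste0(u, substr(u, 1, 8)),
                     provenance = "denovo", is_cyclic = TRUE,
                     unit_length = 20L, stringsAsFactors = FALSE)
  mr2 <- prepare_mapping_reference(lib2, read_length = 100)
  expect_true(mr2$tiled)
  expect_equal(mr2$map_length %% 20, 0)
})

test_that("modal depth follows the histogram argmax with ties upward", {
  prof <- list(a = rep(40L, 1000))
  expect_equal(modal_depth(prof), 40)
  prof2 <- list(a = c(rep(0L, 500), rep(40L, 600), rep(80L, 10)))
  expect_equal(modal_depth(prof2, min_depth = 1), 40)
  prof3 <- list(a = c(rep(10L, 50), rep(30L, 50), rep(2L, 5)))
  expect_equal(modal_depth(prof3, min_depth = 5), 30)  # tie broken upward
  expect_error(modal_depth(list(a = rep(3L, 10)), min_depth = 10), "modal")
})

test_that("interval scanning accumulates eligible bases into v-sized chunks", {
  d1 <- c(rep(0, 100), rep(50, 12000), rep(0, 50))
  d2 <- rep(0, length(d1))
  iv <- scan_intervals(list(s = d1), list(s = d2),
                       enrichment_params(v = 5000, l = 0, a = 10, b = 10))
  expect_equal(nrow(iv), 3)
  expect_equal(iv$eligible_bases, c(5000, 5000, 2000))
  expect_equal(sum(iv$eligible_bases), 12000)  # conservation
  expect_equal(iv$start[1], 100)
  expect_equal(iv$end[3], 12100)
  expect_true(all(iv$mean_depth_1 == 50))
  # no eligible bases -> no intervals
  iv0 <- scan_intervals(list(s = rep(1, 100)), list(s = rep(2, 100)),
                        enrichment_params(a = 10, b = 10))
  expect_equal(nrow(iv0), 0)
})

test_that("eligibility is an OR of the two minima and caps truncate depth", {
  d1 <- c(rep(0, 10), rep(5, 20))    # never reaches a = 10
  d2 <- c(rep(0, 10), rep(12, 20))   # sample-2 depth makes bases eligible
  iv <- scan_intervals(list(s = d1), list(s = d2),
                       enrichment_params(v = 100, l = 0, a = 10, b = 10))
  expect_equal(iv$eligible_bases, 20)
  expect_equal(iv$mean_depth_1, 5)
  # values above the cap contribute the cap to the mean
  d3 <- rep(100, 50)
  iv2 <- scan_intervals(list(s = d3), list(s = rep(0, 50)),
                        enrichment_params(v = 100, a = 10, b = 10, A = 60, B = 60))
  expect_equal(iv2$mean_depth_1, 60)
})

test_that("enrichment scores standardize by modal depth with a finite floor", {
  expect_equal(enrichment_score(40, 40, 40, 40), 0)
  expect_equal(enrichment_score(80, 40, 40, 40), 1)
  # standardized ratio of 64 is a score of 6
  expect_equal(enrichment_score(64 * 73, 73, 73, 73), 6)
  # zero somatic coverage is floored, keeping the score finite
  sc <- enrichment_score(100, 0, 40, 40, floor = 1)
  expect_true(is.finite(sc))
  expect_equal(sc, log2((100 / 40) / (1 / 40)))
  expect_error(enrichment_score(10, 10, 0, 40), "modal")
})

test_that("span estimation follows length x coverage / modal coverage", {
  expect_equal(estimate_span(1000, 73, 73), 1000)
  expect_equal(estimate_span(1000, 0, 73), 0)
  expect_equal(estimate_span(5000, 146, 73), 10000)
  # linear in both arguments
  expect_equal(estimate_span(2000, 50, 25), 2 * estimate_span(1000, 50, 25))
  expect_equal(estimate_span(1000, 100, 25), 2 * estimate_span(1000, 50, 25))
})

test_that("the germline filter is strict on both thresholds", {
  iv <- data.frame(sequence_id = letters[1:4],
                   enrichment_score = c(5.1, 5.0, 8.0, 6.0),
                   estimated_span = c(41000, 100000, 40000, 50000))
  kept <- filter_germline(iv, filter_params(min_score = 5, min_span = 40000))
  expect_identical(kept$sequence_id, c("a", "d"))
  # stable input order
  expect_identical(kept$sequence_id,
                   iv$sequence_id[iv$enrichment_score > 5 &
                                    iv$estimated_span > 40000])
})

test_that("unit-copy flooring makes absent-in-soma scores equal log2(copies)", {
  # 200 unit copies of a 25 bp unit on a 500 bp tiled reference at modal 40
  iv <- data.frame(sequence_id = "sat", start = 0, end = 500,
                   eligible_bases = 500,
                   mean_depth_1 = 200 * 25 / 500 * 40, mean_depth_2 = 0)
  sc <- score_intervals(iv, modal1 = 40, modal2 = 40,
                        unit_lengths = c(sat = 25))
  expect_equal(sc$enrichment_score, log2(200))
  expect_equal(sc$estimated_span, 200 * 25)
})
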