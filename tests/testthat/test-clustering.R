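# Greedy family clustering and cross-alignment merging.

# Build sequences sharing exactly n_blocks common 60 bp blocks, at shuffled
# offsets so each shared block is a separate alignment hit.
blocky_pair <- function(n_blocks, seed) {
  withr::with_seed(seed, {
    blocks <- replicate(n_blocks, rdna(60))
    a <- paste(c(rbind(replicate(n_blocks, rdna(90)), blocks),
                 rdna(90)), collapse = "")
    ord <- rev(seq_len(n_blocks))
    b <- paste(c(rbind(replicate(n_blocks, rdna(130)), blocks[ord]),
                 rdna(70)), collapse = "")
    c(a, b)
  })
}

test_that("identical sequences form one cluster; unrelated stay apart", {
  s <- rdna(300, seed = 111)
  lib <- tiny_library(c(s, s, rdna(300, seed = 112)))
  cl <- greedy_cluster(lib)
  mem <- cluster_membership(cl)
  expect_equal(length(cl), 2)
  expect_setequal(mem$member_id[mem$cluster_id == mem$cluster_id[1]],
                  c("s01", "s02"))
})

test_that("clusters recover planted families at 10% mutual divergence", {
  withr::with_seed(113, {
    cores <- replicate(3, rdna(320))
    members <- unlist(lapply(seq_along(cores), function(i) {
      vapply(1:4, function(j) mutate_seq(cores[i], 0.05), "")
    }))
  })
  lib <- tiny_library(members)
  truth_family <- rep(1:3, each = 4)
  cl <- greedy_cluster(lib)
  mem <- cluster_membership(cl)
  expect_equal(length(cl), 3)
  got <- mem$cluster_id[match(lib$id, mem$member_id)]
  expect_equal(length(unique(paste(truth_family, got))), 3)
  # partition: every input appears exactly once
  expect_setequal(mem$member_id, lib$id)
  expect_false(anyDuplicated(mem$member_id) > 0)
})

test_that("representatives are the longest members, processed first-fit", {
  withr::with_seed(114, {
    long <- rdna(500)
    short <- mutate_seq(substr(long, 1, 300), 0.05)
  })
  lib <- tiny_library(c(short, long))
  cl <- greedy_cluster(lib)
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$representative_id, "s02")  # the 500 bp founder
})

test_that("cross-merge requires at least four hits and is transitive", {
  ab <- blocky_pair(4, seed = 115)   # A and B share 4 blocks
  cd <- blocky_pair(3, seed = 116)   # C and D share only 3
  lib <- data.frame(id = c("A", "B", "C", "D"),
                    sequence = c(ab, cd), provenance = "denovo",
                    is_cyclic = FALSE, unit_length = NA_integer_,
                    stringsAsFactors = FALSE)
  hm <- germsat:::cross_hit_matrix(lib, cluster_params())
  expect_gte(hm["A", "B"], 4)
  expect_equal(unname(hm["C", "D"]), 3)
  expect_equal(unname(hm["A", "C"]), 0)
  singles <- greedy_cluster(lib)
  expect_equal(length(singles), 4)
  merged <- cross_merge(singles, lib)
  mem <- cluster_membership(merged)
  expect_equal(length(merged), 3)
  expect_equal(mem$cluster_id[mem$member_id == "A"],
               mem$cluster_id[mem$member_id == "B"])
  expect_false(mem$cluster_id[mem$member_id == "C"] ==
                 mem$cluster_id[mem$member_id == "D"])
  ph <- attr(merged, "pair_hits")
  expect_true(is.data.frame(ph))
  expect_true(any(ph$merged))
})

test_that("union-find closes merge chains A~B~C into one cluster", {
  withr::with_seed(117, {
    blocks_ab <- replicate(4, rdna(60))
    blocks_bc <- replicate(4, rdna(60))
    mk <- function(blocks) paste(c(rbind(replicate(4, rdna(100)), blocks),
                                   rdna(80)), collapse = "")
    a <- mk(blocks_ab)
    b <- paste0(mk(rev(blocks_ab)), mk(blocks_bc))
    cc <- mk(rev(blocks_bc))
  })
  lib <- data.frame(id = c("A", "B", "C"), sequence = c(a, b, cc),
                    provenance = "denovo", is_cyclic = FALSE,
                    unit_length = NA_integer_, stringsAsFactors = FALSE)
  hm <- germsat:::cross_hit_matrix(lib, cluster_params())
  expect_gte(hm["A", "B"], 4)
  expect_gte(hm["B", "C"], 4)
  expect_equal(unname(hm["A", "C"]), 0)
  merged <- cross_merge(greedy_cluster(lib), lib)
  expect_equal(length(merged), 1)
  expect_setequal(merged[[1]]$member_ids, c("A", "B", "C"))
  expect_equal(merged[[1]]$representative_id, "B")  # longest member
})

test_that("merging never increases cluster count; infinite threshold is identity", {
  withr::with_seed(118, seqs <- replicate(5, rdna(260)))
  lib <- tiny_library(seqs)
  cl <- greedy_cluster(lib)
  same <- cross_merge(cl, lib, cluster_params(merge_min_hits = Inf))
  expect_equal(length(same), length(cl))
  expect_identical(lapply(same, `[[`, "member_ids"),
                   lapply(cl, `[[`, "member_ids"))
})

test_that("the cluster report sums member spans and flags singletons", {
  lib <- tiny_library(c(rdna(300, seed = 119), rdna(200, seed = 120),
                        rdna(180, seed = 121)))
  cl <- list(
    list(cluster_id = "cluster_001", representative_id = "s01",
         member_ids = c("s01", "s02", "s03")),
    list(cluster_id = "cluster_002", representative_id = "s02",
         member_ids = "s02"))
  class(cl) <- "repeat_clusters"
  spans <- c(s01 = 10000, s02 = 20000, s03 = 30000)
  rep <- cluster_report(cl, spans)
  expect_equal(rep$combined_span[rep$cluster_id == "cluster_001"], 60000)
  expect_equal(rep$n_members[rep$cluster_id == "cluster_001"], 3)
  expect_true(rep$singleton[rep$cluster_id == "cluster_002"])
  expect_false(is.unsorted(rev(rep$combined_span)))
})

test_that("clustering is deterministic for a fixed input", {
  withr::with_seed(122, {
    base <- replicate(2, rdna(300))
    seqs <- c(vapply(1:3, function(i) mutate_seq(base[1], 0.08), ""),
              vapply(1:3, function(i) mutate_seq(base[2], 0.08), ""))
  })
  lib <- tiny_library(seqs)
  a <- cluster_membership(cross_merge(greedy_cluster(lib), lib))
  b <- cluster_membership(cross_merge(greedy_cluster(lib), lib))
  expect_identical(a, b)
})
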