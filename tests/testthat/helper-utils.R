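# Shared fixture helpers: all fixtures are generated in code under fixed
# seeds; nothing is read from disk.

rdna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Substitute a given fraction of positions (distinct positions, never the
# original base), so pairwise identity is controlled exactly.
mutate_seq <- function(s, frac, seed = NULL) {
  gen <- function() {
    n <- nchar(s)
    pos <- sample.int(n, round(frac * n))
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# All k-length windows of a string.
seq_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

# Independent brute-force canonical k-mer counter (dictionary scan).
brute_kmer_counts <- function(seqs, k) {
  words <- unlist(lapply(seqs, function(s) {
    parts <- strsplit(s, "[^ACGT]+")[[1]]
    unlist(lapply(parts, seq_windows, k = k), use.names = FALSE)
  }), use.names = FALSE)
  if (!length(words)) {
    return(data.frame(kmer = character(0), count = numeric(0)))
  }
  canon <- canonical_kmer(words)
  tab <- table(canon)
  out <- data.frame(kmer = names(tab), count = as.numeric(tab),
                    stringsAsFactors = FALSE)
  out[order(out$kmer), , drop = FALSE]
}

# Tiny repeat library constructor for alignment/cluster tests.
tiny_library <- function(seqs, prefix = "s") {
  data.frame(id = sprintf("%s%02d", prefix, seq_along(seqs)),
             sequence = unname(seqs), provenance = "denovo",
             is_cyclic = FALSE, unit_length = NA_integer_,
             stringsAsFactors = FALSE)
}
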