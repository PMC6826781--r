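# Packaged simulation scenarios. The standard scenario reproduces the study
# conditions at desk scale: two ~2 Mb genomes sharing three abundant
# pericentromeric satellite families, with six additional germline-restricted
# tandem families (core units spanning 13-57 bp, >= 60 kb planted span each,
# standardized copy ratio >= 64), sequenced to 40x with substitution-only
# paired reads.

# A unit is acceptable when its own tiling has no sub-period (so detected
# period equals the unit length) and it shares no 11-mer with the units
# already chosen (families must not cross-match).
pick_unit <- function(len, seed, existing_words) {
  for (try in 0:50) {
    u <- make_repeat_unit(len, gc_fraction = 0.45, seed = seed + try * 7919L)
    tiled <- strrep(u, ceiling(300 / len))
    ann <- detect_core_unit(tiled, period_range = c(5L, len), min_score = 0.95)
    if (is.na(ann$core_unit_length) || ann$core_unit_length != len) next
    dbl <- paste0(u, u)
    i <- seq_len(2L * len - 10L)
    words <- unique(c(substring(dbl, i, i + 10L),
                      substring(revcomp(dbl), i, i + 10L)))
    if (any(words %in% existing_words)) next
    return(list(unit = u, words = words))
  }
  stop("could not generate a distinct unit of length ", len)
}

#' The packaged standard scenario
#'
#' @param seed integer master seed; every downstream randomization derives
#'   from it.
#' @param backbone_length genome length in bp per genome.
#' @param n_sequences scaffolds per genome.
#' @param coverage read coverage per sample.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param restricted_span target planted span per restricted family in bp.
#' @param shared_span target planted span per shared family in bp.
#' @return list describing the scenario: `families` (list of
#'   [family_spec()]), `reference` and `known` libraries, `read_config`
#'   template, and the structural parameters.
#' @export
standard_scenario <- function(seed = 1L, backbone_length = 2e6L,
                              n_sequences = 2L, coverage = 40,
                              read_length = 150L, error_rate = 0.002,
                              restricted_span = 63000, shared_span = 50000) {
  restricted_units <- c(13L, 21L, 29L, 37L, 46L, 57L)
  shared_units <- c(120L, 150L, 180L)
  words <- character(0)
  units <- list()
  all_lens <- c(restricted_units, shared_units)
  for (i in seq_along(all_lens)) {
    pk <- pick_unit(all_lens[i], seed * 131L + i * 1009L, words)
    units[[i]] <- pk$unit
    words <- c(words, pk$words)
  }
  families <- list()
  for (i in seq_along(restricted_units)) {
    u <- restricted_units[i]
    families[[length(families) + 1L]] <- family_spec(
      family_id = sprintf("germfam%d_u%d", i, u), unit_seq = units[[i]],
      copies_germline = as.integer(ceiling(restricted_span / u)),
      copies_somatic = 0L, indel_rate = 0.02, substitution_rate = 0.03,
      inverted_cassette_prob = 0.1, cassette_size = 20L)
  }
  for (j in seq_along(shared_units)) {
    u <- shared_units[j]
    i <- length(restricted_units) + j
    copies <- as.integer(ceiling(shared_span / u))
    families[[length(families) + 1L]] <- family_spec(
      family_id = sprintf("sharedfam%d_u%d", j, u), unit_seq = units[[i]],
      copies_germline = copies, copies_somatic = copies,
      indel_rate = 0.02, substitution_rate = 0.03,
      inverted_cassette_prob = 0.1, cassette_size = 20L)
  }
  # reference repeat models: what a repeat annotator run on the germline
  # reference assembly would emit -- tiled unit models of every family,
  # plus two decoy models absent from the genomes
  ref_ids <- vapply(families, function(f) paste0("ref_", f$family_id), "")
  ref_seqs <- vapply(families, function(f) {
    strrep(f$unit_seq, ceiling(240 / nchar(f$unit_seq)))
  }, "")
  decoys <- with_seed(seed * 997L + 13L, random_dna(c(400L, 400L)))
  reference <- data.frame(
    id = c(ref_ids, "ref_decoy1", "ref_decoy2"),
    sequence = c(ref_seqs, decoys),
    provenance = "reference", stringsAsFactors = FALSE)
  # a previously characterized germline repeat (Germ1 analogue): the first
  # restricted family's unit, independently tiled
  known <- data.frame(
    id = "germ1_like",
    sequence = strrep(families[[1L]]$unit_seq,
                      ceiling(260 / nchar(families[[1L]]$unit_seq))),
    provenance = "known", stringsAsFactors = FALSE)
  list(families = families, reference = reference, known = known,
       backbone_length = as.integer(backbone_length),
       n_sequences = as.integer(n_sequences),
       read_config = read_sim_config(read_length = read_length,
                                     mean_coverage = coverage,
                                     error_rate = error_rate, paired = TRUE,
                                     insert_mean = 400, insert_sd = 30,
                                     seed = seed),
       seed = as.integer(seed))
}

#' Simulate a scenario to disk
#'
#' Builds the genome pair, writes genomes, reference/known FASTA, the truth
#' TSV and paired FASTQ for both tissues.
#'
#' @param scenario a [standard_scenario()]-style list.
#' @param out_dir output directory (created if needed).
#' @return list of paths (`germline_fasta`, `somatic_fasta`,
#'   `reads_germline`, `reads_somatic`, `reference_fasta`, `known_fasta`,
#'   `truth_tsv`) plus the in-memory `truth` and `genomes`.
#' @export
simulate_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- scenario$seed
  gp <- build_genome_pair(scenario$families, scenario$backbone_length,
                          n_sequences = scenario$n_sequences,
                          seed = seed, min_gap = 2000L)
  paths <- list(
    germline_fasta = file.path(out_dir, "germline.fasta"),
    somatic_fasta = file.path(out_dir, "somatic.fasta"),
    reference_fasta = file.path(out_dir, "reference_repeats.fasta"),
    known_fasta = file.path(out_dir, "known_repeats.fasta"),
    truth_tsv = file.path(out_dir, "truth.tsv"))
  write_fasta(gp$germline, paths$germline_fasta)
  write_fasta(gp$somatic, paths$somatic_fasta)
  ref <- scenario$reference
  rs <- ref$sequence; names(rs) <- ref$id
  write_fasta(rs, paths$reference_fasta)
  ks <- scenario$known$sequence; names(ks) <- scenario$known$id
  write_fasta(ks, paths$known_fasta)
  write_truth(gp$truth, paths$truth_tsv)
  cfg_g <- scenario$read_config; cfg_g$seed <- seed + 101L
  cfg_s <- scenario$read_config; cfg_s$seed <- seed + 202L
  paths$reads_germline <- as.character(
    simulate_reads(gp$germline, cfg_g, file.path(out_dir, "germline")))
  paths$reads_somatic <- as.character(
    simulate_reads(gp$somatic, cfg_s, file.path(out_dir, "somatic")))
  c(paths, list(truth = gp$truth, genomes = gp))
}
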