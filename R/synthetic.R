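# Synthetic two-genome satellite scenarios: planted tandem repeat families
# (shared pericentromeric plus germline-restricted), read simulation, and a
# ground-truth table so downstream recovery is testable without external data.
#
# Coordinates are 0-based half-open throughout; orientation is "+"/"-".

#' Specify a planted satellite family
#'
#' A family is defined by a short core unit that is repeated head-to-tail.
#' Copies of the unit diverge by per-base substitutions, unit junctions can
#' carry small insertions or deletions, and blocks of `cassette_size` units
#' can be emitted in reverse-complement orientation (inverted cassettes).
#' Germline-restricted families have `copies_somatic = 0`.
#'
#' @param family_id label, unique within a scenario.
#' @param unit_seq DNA string of the core unit (>= 5 bp).
#' @param copies_germline,copies_somatic planted unit copy numbers per genome.
#' @param indel_rate per-junction probability of a 1-3 bp insertion/deletion.
#' @param substitution_rate per-base substitution probability per unit copy.
#' @param inverted_cassette_prob probability that a cassette of units is
#'   emitted as its reverse complement.
#' @param cassette_size number of consecutive units per cassette.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(family_id, unit_seq,
                        copies_germline, copies_somatic = 0L,
                        indel_rate = 0, substitution_rate = 0,
                        inverted_cassette_prob = 0, cassette_size = 20L) {
  stopifnot(is.character(family_id), length(family_id) == 1L)
  if (nchar(unit_seq) < 5)
    stop("unit length must be >= 5 bp (family '", family_id, "')")
  rates <- c(indel_rate, substitution_rate, inverted_cassette_prob)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1] (family '", family_id, "')")
  if (copies_germline < 0 || copies_somatic < 0)
    stop("copy numbers must be >= 0")
  structure(list(
    family_id = family_id, unit_seq = toupper(unit_seq),
    copies_germline = as.integer(copies_germline),
    copies_somatic = as.integer(copies_somatic),
    indel_rate = indel_rate, substitution_rate = substitution_rate,
    inverted_cassette_prob = inverted_cassette_prob,
    cassette_size = as.integer(cassette_size)
  ), class = "family_spec")
}

#' Generate a random repeat core unit
#'
#' @param length unit length in bp (5-500; observed satellite cores in
#'   germline-restricted repeats run as short as 13-57 bp).
#' @param gc_fraction target GC content.
#' @param seed integer seed; the same call always returns the same unit.
#' @return a DNA string of exactly `length` bases.
#' @export
make_repeat_unit <- function(length, gc_fraction = 0.5, seed = 1L) {
  if (length < 5 || length > 500)
    stop("unit length must be between 5 and 500 bp")
  with_seed(seed, random_dna(length, gc = gc_fraction))
}

# Mutate unit copies: per-base substitutions, then an optional small indel at
# the unit's 3' junction. Returns a character vector of realized unit copies.
mutate_units <- function(unit, copies, substitution_rate, indel_rate) {
  units <- rep.int(unit, copies)
  u <- nchar(unit)
  if (substitution_rate > 0) {
    nmut <- stats::rbinom(copies, u, substitution_rate)
    for (i in which(nmut > 0L)) {
      pos <- sample.int(u, nmut[i])
      s <- units[i]
      for (p in pos) {
        cur <- substr(s, p, p)
        substr(s, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
      units[i] <- s
    }
  }
  if (indel_rate > 0) {
    has_indel <- stats::runif(copies) < indel_rate
    for (i in which(has_indel)) {
      sz <- sample.int(3L, 1L)
      if (stats::runif(1) < 0.5) {
        units[i] <- paste0(units[i], random_dna(sz))
      } else {
        keep <- max(1L, nchar(units[i]) - sz)
        units[i] <- substr(units[i], 1L, keep)
      }
    }
  }
  units
}

#' Expand a family into a tandem array
#'
#' Concatenates mutated copies of the core unit. Units are grouped into
#' cassettes of `spec$cassette_size`; each cassette is emitted reverse
#' complemented with probability `spec$inverted_cassette_prob`.
#'
#' @param spec a [family_spec()].
#' @param copies number of unit copies to emit (>= 1).
#' @param seed integer seed.
#' @return list with `sequence` (the array), `units` (data.frame of 0-based
#'   half-open unit placements with strand), and `cassettes` (data.frame of
#'   inverted cassette intervals).
#' @export
expand_tandem_array <- function(spec, copies, seed = 1L) {
  stopifnot(inherits(spec, "family_spec"))
  if (copies < 1) stop("copies must be >= 1")
  with_seed(seed, {
    units <- mutate_units(spec$unit_seq, copies,
                          spec$substitution_rate, spec$indel_rate)
    cs <- max(1L, spec$cassette_size)
    grp <- ((seq_len(copies) - 1L) %/% cs) + 1L
    ngrp <- max(grp)
    inverted <- stats::runif(ngrp) < spec$inverted_cassette_prob
    pieces <- character(ngrp)
    unit_rows <- vector("list", ngrp)
    offset <- 0L
    cass <- list()
    for (g in seq_len(ngrp)) {
      idx <- which(grp == g)
      w <- nchar(units[idx])
      block_len <- sum(w)
      if (inverted[g]) {
        pieces[g] <- revcomp(paste(units[idx], collapse = ""))
        # unit order reverses within an inverted cassette
        ends_rev <- cumsum(rev(w))
        starts_rev <- ends_rev - rev(w)
        unit_rows[[g]] <- data.frame(
          start = offset + starts_rev, end = offset + ends_rev,
          strand = "-", stringsAsFactors = FALSE)
        cass[[length(cass) + 1L]] <- c(offset, offset + block_len)
      } else {
        pieces[g] <- paste(units[idx], collapse = "")
        ends <- cumsum(w)
        unit_rows[[g]] <- data.frame(
          start = offset + ends - w, end = offset + ends,
          strand = "+", stringsAsFactors = FALSE)
      }
      offset <- offset + block_len
    }
    units_df <- do.call(rbind, unit_rows)
    rownames(units_df) <- NULL
    cass_df <- if (length(cass)) {
      m <- do.call(rbind, cass)
      data.frame(start = m[, 1], end = m[, 2])
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
    list(sequence = paste(pieces, collapse = ""),
         units = units_df, cassettes = cass_df)
  })
}

#' Build a germline/somatic genome pair with planted repeat families
#'
#' Both genomes share one random backbone. Every family with
#' `copies_somatic > 0` (shared family) is planted identically, at the same
#' coordinates, in both genomes; germline-restricted families
#' (`copies_somatic = 0`) are planted only in the germline genome, whose
#' array spans replace the corresponding backbone spans (the somatic genome
#' retains pristine backbone there). Family copies are split evenly across
#' `n_sequences` scaffolds, one array per scaffold.
#'
#' @param families list of [family_spec()] objects.
#' @param backbone_length total genome length in bp.
#' @param n_sequences number of scaffolds per genome.
#' @param seed integer seed.
#' @param min_gap minimum backbone gap around each planted array.
#' @return list with `germline` and `somatic` (named character vectors of
#'   scaffold sequences) and `truth`, a data.frame of array-level placements
#'   (family_id, seq_id, start, end, strand, copies in each genome, and the
#'   expected enrichment score log2(copies_germline / max(copies_somatic, 1))).
#'   Unit-level placements and inverted-cassette intervals are attached as
#'   attribute `details`.
#' @export
build_genome_pair <- function(families, backbone_length, n_sequences = 1L,
                              seed = 1L, min_gap = 500L) {
  stopifnot(length(families) > 0, all(vapply(families, inherits, TRUE, "family_spec")))
  ids <- vapply(families, `[[`, "", "family_id")
  if (anyDuplicated(ids)) stop("duplicate family_id")
  with_seed(seed, {
    seq_len_each <- rep(backbone_length %/% n_sequences, n_sequences)
    seq_len_each[n_sequences] <- backbone_length - sum(seq_len_each[-n_sequences])
    seq_ids <- sprintf("seq%d", seq_len(n_sequences))
    backbone <- random_dna(seq_len_each)

    # split each family's copies across scaffolds, realize each array once
    plan <- list()
    for (f in families) {
      cuts <- round(seq(0, f$copies_germline, length.out = n_sequences + 1L))
      per_seq <- diff(cuts)
      for (s in seq_len(n_sequences)) {
        if (per_seq[s] <= 0) next
        arr <- expand_tandem_array(f, per_seq[s],
                                   seed = sample.int(2^30, 1L))
        plan[[length(plan) + 1L]] <- list(
          family = f, seq = s, copies = per_seq[s], array = arr,
          len = nchar(arr$sequence))
      }
    }

    germ <- backbone
    soma <- backbone
    truth_rows <- list()
    details <- list()
    for (s in seq_len(n_sequences)) {
      items <- Filter(function(p) p$seq == s, plan)
      if (!length(items)) next
      items <- items[sample.int(length(items))]  # random order along scaffold
      lens <- vapply(items, `[[`, 0, "len")
      n <- length(items)
      free <- seq_len_each[s] - sum(lens) - (n + 1L) * min_gap
      if (free < 0)
        stop("planted material exceeds backbone on ", seq_ids[s])
      props <- diff(c(0, sort(stats::runif(n)), 1))
      gaps <- min_gap + floor(free * props)[seq_len(n + 1L)]
      pos <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, lens[-n]))
      for (i in seq_len(n)) {
        it <- items[[i]]
        start <- pos[i]
        end <- start + it$len
        substr(germ[s], start + 1L, end) <- it$array$sequence
        restricted <- it$family$copies_somatic == 0L
        if (!restricted) substr(soma[s], start + 1L, end) <- it$array$sequence
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          family_id = it$family$family_id, seq_id = seq_ids[s],
          start = start, end = end, strand = "+",
          copies = it$copies, restricted = restricted,
          stringsAsFactors = FALSE)
        du <- it$array$units
        du$start <- du$start + start; du$end <- du$end + start
        dc <- it$array$cassettes
        if (nrow(dc)) { dc$start <- dc$start + start; dc$end <- dc$end + start }
        details[[length(details) + 1L]] <- list(
          family_id = it$family$family_id, seq_id = seq_ids[s],
          units = du, cassettes = dc)
      }
    }
    truth <- do.call(rbind, truth_rows)
    # per-family summary columns
    fam_copies_g <- vapply(families, `[[`, 0L, "copies_germline")
    fam_copies_s <- vapply(families, `[[`, 0L, "copies_somatic")
    names(fam_copies_g) <- names(fam_copies_s) <- ids
    truth$copies_germline <- fam_copies_g[truth$family_id]
    truth$copies_somatic <- fam_copies_s[truth$family_id]
    fam_units <- vapply(families, `[[`, "", "unit_seq")
    names(fam_units) <- ids
    truth$unit_seq <- fam_units[truth$family_id]
    truth$expected_score <- log2(pmax(truth$copies_germline, 1) /
                                   pmax(truth$copies_somatic, 1))
    names(germ) <- names(soma) <- seq_ids
    attr(truth, "details") <- details
    class(truth) <- c("synthetic_truth", class(truth))
    list(germline = germ, somatic = soma, truth = truth)
  })
}

#' Per-family summary of a truth table
#'
#' @param truth the `truth` data.frame from [build_genome_pair()].
#' @return data.frame with one row per family: realized copies, planted span
#'   per genome, restricted flag, expected enrichment score.
#' @export
truth_family_summary <- function(truth) {
  sp <- split(seq_len(nrow(truth)), truth$family_id)
  out <- do.call(rbind, lapply(names(sp), function(fid) {
    rows <- truth[sp[[fid]], , drop = FALSE]
    data.frame(
      family_id = fid,
      restricted = rows$restricted[1],
      copies_germline = rows$copies_germline[1],
      copies_somatic = rows$copies_somatic[1],
      span_germline = sum(rows$end - rows$start),
      span_somatic = if (rows$restricted[1]) 0L else sum(rows$end - rows$start),
      expected_score = rows$expected_score[1],
      unit_seq = if ("unit_seq" %in% names(rows)) rows$unit_seq[1] else NA_character_,
      stringsAsFactors = FALSE)
  }))
  out[order(out$family_id), , drop = FALSE]
}

#' Configure the read simulator
#'
#' @param read_length read length in bp.
#' @param mean_coverage target fold coverage per genome.
#' @param error_rate per-base substitution error rate (0-0.1).
#' @param paired simulate read pairs from both fragment ends.
#' @param insert_mean,insert_sd fragment size distribution (paired mode).
#' @param seed integer seed.
#' @return an object of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 150L, mean_coverage = 40,
                            error_rate = 0.002, paired = FALSE,
                            insert_mean = 400, insert_sd = 30, seed = 1L) {
  if (mean_coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate > 0.1) stop("error_rate must be in [0, 0.1]")
  if (read_length < 1) stop("read_length must be positive")
  structure(list(read_length = as.integer(read_length),
                 mean_coverage = mean_coverage, error_rate = error_rate,
                 paired = paired, insert_mean = insert_mean,
                 insert_sd = insert_sd, seed = seed),
            class = "read_sim_config")
}

# Vectorized substitution errors: repeatedly apply one random error to every
# read that still has errors pending.
apply_substitutions <- function(reads, n_errors) {
  other <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  while (any(n_errors > 0L)) {
    idx <- which(n_errors > 0L)
    len <- nchar(reads[idx])
    pos <- 1L + floor(stats::runif(length(idx)) * len)
    cur <- substr(reads[idx], pos, pos)
    pick <- 1L + floor(stats::runif(length(idx)) * 3)
    new <- other[cbind(match(cur, rownames(other)), pick)]
    x <- reads[idx]
    substr(x, pos, pos) <- new
    reads[idx] <- x
    n_errors[idx] <- n_errors[idx] - 1L
  }
  reads
}

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions, random strand, substitution-only errors, fixed
#' "I" base qualities. The read count is `round(coverage * genome_size /
#' read_length)` (pairs count as two reads), so the expected base yield
#' matches `mean_coverage` exactly. Deterministic for a fixed seed.
#'
#' @param genome named character vector of sequences, or a FASTA path.
#' @param config a [read_sim_config()].
#' @param out_prefix path prefix for the FASTQ output; `_R1.fastq` /
#'   `_R2.fastq` are appended in paired mode, `.fastq` otherwise.
#' @return character vector of the FASTQ paths written, with attribute
#'   `n_reads`.
#' @export
simulate_reads <- function(genome, config, out_prefix) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome)))
    genome <- read_fasta(genome)
  stopifnot(length(genome) > 0, !is.null(names(genome)))
  rl <- config$read_length
  lens <- nchar(genome)
  if (rl > min(lens))
    stop("read_length exceeds the shortest genome sequence")
  G <- sum(lens)
  with_seed(config$seed, {
    if (config$paired) {
      n_pairs <- max(1L, round(config$mean_coverage * G / (2 * rl)))
      seq_idx <- sample.int(length(genome), n_pairs, replace = TRUE,
                            prob = lens)
      ins <- pmin(pmax(round(stats::rnorm(n_pairs, config$insert_mean,
                                          config$insert_sd)), rl),
                  lens[seq_idx])
      start <- floor(stats::runif(n_pairs) * (lens[seq_idx] - ins + 1))
      flip <- stats::runif(n_pairs) < 0.5
      r1 <- substring(genome[seq_idx], start + 1L, start + rl)
      r2 <- revcomp(substring(genome[seq_idx], start + ins - rl + 1L,
                              start + ins))
      tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
      r1 <- apply_substitutions(r1, stats::rbinom(n_pairs, rl, config$error_rate))
      r2 <- apply_substitutions(r2, stats::rbinom(n_pairs, rl, config$error_rate))
      nm <- sprintf("read%07d", seq_len(n_pairs))
      p1 <- paste0(out_prefix, "_R1.fastq")
      p2 <- paste0(out_prefix, "_R2.fastq")
      write_fastq(r1, paste0(nm, "/1"), p1)
      write_fastq(r2, paste0(nm, "/2"), p2)
      structure(c(p1, p2), n_reads = 2L * n_pairs)
    } else {
      n <- max(1L, round(config$mean_coverage * G / rl))
      seq_idx <- sample.int(length(genome), n, replace = TRUE, prob = lens)
      start <- floor(stats::runif(n) * (lens[seq_idx] - rl + 1))
      reads <- substring(genome[seq_idx], start + 1L, start + rl)
      minus <- stats::runif(n) < 0.5
      reads[minus] <- revcomp(reads[minus])
      reads <- apply_substitutions(reads, stats::rbinom(n, rl, config$error_rate))
      p <- paste0(out_prefix, ".fastq")
      write_fastq(reads, sprintf("read%07d", seq_len(n)), p)
      structure(p, n_reads = n)
    }
  })
}

#' Write a truth table as TSV
#' @param truth truth data.frame from [build_genome_pair()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
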