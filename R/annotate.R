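# Structural annotation of repeat families: tandem core unit detection,
# inverted cassette discovery, scaffold assignment, and somatic-abundance
# ranking (centromeric candidates).

#' Detect the tandem core unit of a sequence
#'
#' Alignment-free period detection: for every candidate period p the
#' self-match fraction under shift p (fraction of positions i with
#' base(i) == base(i + p)) is computed; the smallest p scoring at least
#' `min_score` is reported as the core unit length, with a column-majority
#' consensus. Random sequence stays near 0.25 under every shift, so
#' qualifying periods indicate genuine tandem structure. Note that any
#' multiple of the true period also qualifies; reporting the smallest
#' qualifying p is the package's convention.
#'
#' @param sequence DNA string (length at least `2 * period_range[1]`).
#' @param period_range integer vector `c(min, max)` of candidate periods in
#'   bp; the default brackets the 13-57 bp cores seen in germline-restricted
#'   satellites.
#' @param min_score minimum self-match fraction.
#' @return list of class `tandem_annotation`: `core_unit_length` (NA when no
#'   period qualifies), `core_consensus`, `periodicity_score` (score of the
#'   chosen period, or the maximum observed), and `score_curve` (data.frame
#'   period/score).
#' @export
detect_core_unit <- function(sequence, period_range = c(5L, 200L),
                             min_score = 0.8) {
  n <- nchar(sequence)
  pmin_ <- max(1L, as.integer(period_range[1]))
  if (n < 2L * pmin_)
    stop("sequence too short for period detection (need >= ", 2L * pmin_, " bp)")
  pmax_ <- min(as.integer(period_range[2]), n %/% 2L)
  raw <- charToRaw(toupper(sequence))
  periods <- seq.int(pmin_, pmax_)
  scores <- vapply(periods, function(p) {
    mean(raw[seq_len(n - p)] == raw[seq.int(p + 1L, n)])
  }, 0)
  qualifying <- which(scores >= min_score)
  if (length(qualifying)) {
    p <- periods[qualifying[1L]]
    score <- scores[qualifying[1L]]
    chars <- strsplit(toupper(sequence), "")[[1L]]
    phase <- ((seq_len(n) - 1L) %% p) + 1L
    cons <- vapply(seq_len(p), function(ph) {
      tab <- table(factor(chars[phase == ph], levels = DNA_BASES))
      names(tab)[which.max(tab)]  # ties resolve to the first (lexicographic)
    }, "")
    consensus <- paste(cons, collapse = "")
  } else {
    p <- NA_integer_
    score <- if (length(scores)) max(scores) else NA_real_
    consensus <- NA_character_
  }
  structure(list(core_unit_length = p, core_consensus = consensus,
                 periodicity_score = score,
                 score_curve = data.frame(period = periods, score = scores)),
            class = "tandem_annotation")
}

#' Find inverted cassettes within a sequence
#'
#' Locally aligns the sequence against its own reverse complement and
#' reports non-self-overlapping interval pairs with identity >= 0.8 and
#' length >= `min_cassette`: the signature of a tandem block duplicated in
#' inverted orientation. Pairs are reported once, left interval first.
#'
#' @param sequence DNA string.
#' @param min_cassette minimum cassette length in bp.
#' @param params a [merge_params()] (seed/score settings).
#' @param min_identity minimum alignment identity for a pair.
#' @return data.frame `left_start`, `left_end`, `right_start`, `right_end`,
#'   `identity`, `score` (0-based half-open intervals on the input).
#' @export
find_inverted_cassettes <- function(sequence, min_cassette = 100L,
                                    params = merge_params(max_word_occ = 50L,
                                                          max_clusters = 2000L),
                                    min_identity = 0.8) {
  n <- nchar(sequence)
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      identity = numeric(0), score = numeric(0))
  if (n < 2L * min_cassette) return(empty)
  rc <- revcomp(sequence)
  h <- local_align(sequence, rc, params, both_strands = FALSE)
  if (!nrow(h)) return(empty)
  # map subject (revcomp) coordinates back onto the input
  ms <- n - h$send
  me <- n - h$sstart
  id_ok <- h$identity >= min_identity
  h <- h[id_ok, , drop = FALSE]
  ms <- ms[id_ok]; me <- me[id_ok]
  if (!nrow(h)) return(empty)
  # a hit whose two intervals overlap is a palindrome spanning its own
  # center: split it at the anti-diagonal midpoint into the two arms
  overlap <- !(h$qend <= ms | me <= h$qstart)
  mid <- (h$qstart + me) %/% 2L
  l_start <- ifelse(overlap, h$qstart, pmin(h$qstart, ms))
  l_end <- ifelse(overlap, mid, ifelse(h$qstart <= ms, h$qend, me))
  r_start <- ifelse(overlap, mid, ifelse(h$qstart <= ms, ms, h$qstart))
  r_end <- ifelse(overlap, me, pmax(h$qend, me))
  out <- data.frame(
    left_start = l_start, left_end = l_end,
    right_start = r_start, right_end = r_end,
    identity = h$identity, score = h$score)
  out <- out[pmin(out$left_end - out$left_start,
                  out$right_end - out$right_start) >= min_cassette, ,
             drop = FALSE]
  # the pair and its mirror are the same finding; keep the better-scoring copy
  key <- paste(out$left_start, out$left_end, out$right_start, out$right_end)
  out <- out[order(-out$score, key), , drop = FALSE]
  out <- out[!duplicated(paste(out$left_start, out$left_end,
                               out$right_start, out$right_end)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a repeat to its best-matching genomic scaffold
#'
#' Counts local-alignment hits that each cover at least `min_fraction` of
#' the repeat's bases, per scaffold; the scaffold with the most qualifying
#' hits wins (ties broken by summed hit score). Unassigned when no
#' qualifying hit exists.
#'
#' @param repeat_seq DNA string of the repeat.
#' @param scaffolds named character vector of scaffold sequences.
#' @param min_fraction minimum fraction of repeat bases aligned per hit.
#' @param params a [merge_params()].
#' @return data.frame row: `scaffold_id` (NA when unassigned), `hit_count`,
#'   `fraction_bases_aligned` (best qualifying hit).
#' @export
assign_scaffold <- function(repeat_seq, scaffolds, min_fraction = 0.80,
                            params = merge_params(max_word_occ = 200L,
                                                  max_clusters = 400L)) {
  stopifnot(length(scaffolds) > 0, !is.null(names(scaffolds)))
  best <- list(id = NA_character_, count = 0L, frac = NA_real_, score = -Inf)
  for (sid in sort(names(scaffolds))) {
    h <- local_align(repeat_seq, scaffolds[[sid]], params)
    if (!nrow(h)) next
    qual <- h[h$aligned_query_fraction >= min_fraction, , drop = FALSE]
    cnt <- nrow(qual)
    if (cnt == 0L) next
    tot <- sum(qual$score)
    if (cnt > best$count || (cnt == best$count && tot > best$score)) {
      best <- list(id = sid, count = cnt,
                   frac = max(qual$aligned_query_fraction), score = tot)
    }
  }
  data.frame(scaffold_id = best$id, hit_count = best$count,
             fraction_bases_aligned = best$frac, stringsAsFactors = FALSE)
}

#' Rank library sequences by somatic coverage
#'
#' Repeats with the highest somatic read coverage are centromeric-satellite
#' candidates (the study's Pm-rep1..3 were nominated this way).
#'
#' @param library a `repeat_library` data.frame.
#' @param somatic_profiles `coverage_profiles` of the somatic sample over
#'   the library (mapping reference ids must match library ids).
#' @param top_n number of top repeats to return.
#' @return data.frame `id`, `mean_somatic_depth`, ordered by depth
#'   descending (ties by id).
#' @export
rank_by_somatic_coverage <- function(library, somatic_profiles, top_n = 3L) {
  library <- assert_library(library)
  depth <- if (inherits(somatic_profiles, "coverage_profiles"))
    somatic_profiles$depth else somatic_profiles
  md <- vapply(library$id, function(id) {
    d <- depth[[id]]
    if (is.null(d) || !length(d)) NA_real_ else mean(d)
  }, 0)
  out <- data.frame(id = library$id, mean_somatic_depth = md,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$mean_somatic_depth), , drop = FALSE]
  out <- out[order(-out$mean_somatic_depth, out$id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
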