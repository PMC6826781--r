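# Per-base coverage of two read sets over a repeat library (or scaffolds),
# interval scanning, enrichment scoring and the germline filter.

#' Read-placement parameters for coverage computation
#'
#' @param seed_len exact seed length used to place reads.
#' @param step offset step between probed seed positions within a read.
#' @param max_diags number of top-voted candidate diagonals rescored per read.
#' @param min_match_frac minimum fraction of matching bases over the aligned
#'   span for a placement to count.
#' @param max_occ cap on indexed positions per seed word (bounds work on
#'   high-copy satellite seeds).
#' @return list of class `coverage_params`.
#' @export
coverage_params <- function(seed_len = 19L, step = 9L, max_diags = 8L,
                            min_match_frac = 0.8, max_occ = 64L) {
  structure(list(seed_len = as.integer(seed_len), step = as.integer(step),
                 max_diags = as.integer(max_diags),
                 min_match_frac = min_match_frac,
                 max_occ = as.integer(max_occ)),
            class = "coverage_params")
}

#' Prepare a repeat library for read mapping
#'
#' Short tandem consensi bias depth estimates because reads cannot align
#' end-to-end on a reference shorter than the read. Any sequence shorter
#' than twice the read length whose tandem period is detectable (cyclic
#' assembly products use their recorded period; others are probed with
#' [detect_core_unit()]) is tiled from its core consensus to at least
#' `max(2 * read_length, read_length + 2 * period)`. Depths, spans and
#' scores downstream refer to the tiled (mapping) length, which keeps the
#' span formula self-consistent.
#'
#' @param library a `repeat_library` data.frame.
#' @param read_length read length of the data to be mapped.
#' @param min_periodic_score periodicity score required to tile a
#'   non-cyclic sequence.
#' @return data.frame `id`, `map_sequence`, `map_length`, `unit_length`
#'   (detected core period; the full length for non-periodic sequences),
#'   `tiled` flag.
#' @export
prepare_mapping_reference <- function(library, read_length,
                                      min_periodic_score = 0.8) {
  library <- assert_library(library)
  n <- nrow(library)
  map_seq <- character(n)
  unit_len <- integer(n)
  tiled <- logical(n)
  for (i in seq_len(n)) {
    s <- library$sequence[i]
    L <- nchar(s)
    p <- NA_integer_
    unit <- NULL
    if (isTRUE(library$is_cyclic[i]) && !is.na(library$unit_length[i])) {
      p <- library$unit_length[i]
      unit <- substr(s, 1L, p)
    } else if (L >= 10L) {
      ann <- detect_core_unit(s, period_range = c(5L, max(5L, L %/% 2L)),
                              min_score = min_periodic_score)
      if (!is.na(ann$core_unit_length)) {
        p <- ann$core_unit_length
        unit <- ann$core_consensus
      }
    }
    if (!is.na(p) && (L < read_length + 2L * p || isTRUE(library$is_cyclic[i]))) {
      target <- max(2L * read_length, read_length + 2L * p)
      reps <- ceiling(target / p)
      map_seq[i] <- strrep(unit, reps)
      unit_len[i] <- p
      tiled[i] <- TRUE
    } else {
      map_seq[i] <- s
      unit_len[i] <- if (!is.na(p)) p else L
      tiled[i] <- FALSE
    }
  }
  data.frame(id = library$id, map_sequence = map_seq,
             map_length = nchar(map_seq), unit_length = unit_len,
             tiled = tiled, stringsAsFactors = FALSE)
}

#' Compute per-base coverage of a read set over a reference set
#'
#' Each read (and its reverse complement) is seeded against the reference
#' index; the top-voted diagonals are rescored ungapped and the read is
#' placed at its single best location, with ties broken toward the
#' lexicographically smallest reference id, then leftmost position, then
#' forward strand. Depth is incremented over the aligned bases. Reads with
#' no qualifying placement are counted as unplaced.
#'
#' @param reads FASTQ path(s) or a character vector of read sequences.
#' @param reference named character vector of reference sequences (e.g.
#'   `map_sequence` from [prepare_mapping_reference()], or scaffolds).
#' @param params a [coverage_params()].
#' @return object of class `coverage_profiles`: list with `depth` (named
#'   list of integer vectors), `placed`, `unplaced`.
#' @export
compute_coverage <- function(reads, reference, params = coverage_params()) {
  stopifnot(length(reference) > 0, !is.null(names(reference)))
  ord <- order(names(reference))  # index order encodes the id tie-break
  reference <- reference[ord]
  ix <- cpp_build_index(unname(reference), params$seed_len, params$max_occ)
  res <- if (length(reads) && all(file.exists(reads))) {
    cpp_map_fastq(ix, reads, params$min_match_frac, params$step,
                  params$max_diags)
  } else {
    cpp_map_reads(ix, toupper(reads), params$min_match_frac, params$step,
                  params$max_diags)
  }
  depth <- res$depth
  names(depth) <- names(reference)
  structure(list(depth = depth, placed = res$placed,
                 unplaced = res$unplaced, params = params),
            class = "coverage_profiles")
}

#' @export
print.coverage_profiles <- function(x, ...) {
  cat(sprintf("coverage_profiles: %d sequences, %s reads placed, %s unplaced\n",
              length(x$depth), format(x$placed, big.mark = ","),
              format(x$unplaced, big.mark = ",")))
  invisible(x)
}

#' Modal per-base depth of a sample
#'
#' Mode of the pooled per-base depth histogram over all bases with depth at
#' least `min_depth`; ties break toward the larger depth. This is the
#' single-copy standardization constant (the study's "modal sperm coverage
#' = 73" plays this role).
#'
#' @param profiles a `coverage_profiles` object (or plain named list of
#'   integer depth vectors).
#' @param min_depth minimum depth for a base to enter the histogram.
#' @return numeric modal depth.
#' @export
modal_depth <- function(profiles, min_depth = 1L) {
  depth <- if (inherits(profiles, "coverage_profiles")) profiles$depth else profiles
  maxd <- max(vapply(depth, function(d) if (length(d)) max(d) else 0L, 0L))
  if (maxd < min_depth)
    stop("cannot estimate modal depth: no bases with depth >= ", min_depth)
  tab <- numeric(maxd)
  for (d in depth) {
    d <- d[d >= 1L]
    if (length(d)) {
      t <- tabulate(d, nbins = maxd)
      tab <- tab + t
    }
  }
  counts <- tab[min_depth:maxd]
  vals <- seq.int(min_depth, maxd)
  max(vals[counts == max(counts)])
}

#' Interval-generation parameters
#'
#' Defaults are the study's settings: sequences are not split into intervals
#' shorter than 5 kb of eligible bases (v = 5000), intervals of any length
#' are reported (l = 0), bases must reach depth 10 in either sample to be
#' eligible (a = b = 10), and depths are capped at 12 million (A = B).
#'
#' @param v minimum eligible bases per closed interval.
#' @param l minimum eligible bases for the trailing interval to be reported.
#' @param a,b minimum depth in sample 1 / sample 2 for base eligibility
#'   (a base is eligible when either minimum is met).
#' @param A,B depth caps applied before averaging.
#' @return list of class `enrichment_params`.
#' @export
enrichment_params <- function(v = 5000L, l = 0L, a = 10, b = 10,
                              A = 12e6, B = 12e6) {
  stopifnot(v >= l, l >= 0, A >= a, B >= b)
  structure(list(v = as.integer(v), l = as.integer(l), a = a, b = b,
                 A = A, B = B), class = "enrichment_params")
}

#' Scan two coverage profiles into enrichment intervals
#'
#' Per sequence, bases with depth >= a in sample 1 or depth >= b in sample 2
#' are eligible; depths above the caps A/B contribute the cap. Eligible
#' bases accumulate left-to-right into intervals closed at every v eligible
#' bases; a trailing interval with fewer than v eligible bases is reported
#' when its eligible length is at least l. Interval means are over eligible
#' (capped) bases only.
#'
#' @param profile1,profile2 `coverage_profiles` over the same sequences
#'   (sample 1 = germline, sample 2 = soma in the study's orientation).
#' @param params an [enrichment_params()].
#' @return data.frame: `sequence_id`, `start`, `end` (0-based half-open,
#'   spanning first to last eligible base), `eligible_bases`,
#'   `mean_depth_1`, `mean_depth_2`.
#' @export
scan_intervals <- function(profile1, profile2, params = enrichment_params()) {
  d1l <- if (inherits(profile1, "coverage_profiles")) profile1$depth else profile1
  d2l <- if (inherits(profile2, "coverage_profiles")) profile2$depth else profile2
  stopifnot(identical(sort(names(d1l)), sort(names(d2l))))
  rows <- list()
  for (sid in names(d1l)) {
    d1 <- as.numeric(d1l[[sid]])
    d2 <- as.numeric(d2l[[sid]])
    stopifnot(length(d1) == length(d2))
    elig <- which(d1 >= params$a | d2 >= params$b)
    if (!length(elig)) next
    c1 <- pmin(d1[elig], params$A)
    c2 <- pmin(d2[elig], params$B)
    grp <- ((seq_along(elig) - 1L) %/% params$v) + 1L
    ngrp <- max(grp)
    sizes <- tabulate(grp, nbins = ngrp)
    keep <- rep(TRUE, ngrp)
    if (sizes[ngrp] < params$v && sizes[ngrp] < params$l) keep[ngrp] <- FALSE
    m1 <- vapply(split(c1, grp), mean, 0)
    m2 <- vapply(split(c2, grp), mean, 0)
    st <- vapply(split(elig, grp), min, 0) - 1
    en <- vapply(split(elig, grp), max, 0)
    rows[[sid]] <- data.frame(
      sequence_id = sid, start = st[keep], end = en[keep],
      eligible_bases = sizes[keep], mean_depth_1 = m1[keep],
      mean_depth_2 = m2[keep], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(0), start = numeric(0),
                      end = numeric(0), eligible_bases = integer(0),
                      mean_depth_1 = numeric(0), mean_depth_2 = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Germline enrichment score
#'
#' `log2((mean1/modal1) / (max(mean2, floor)/modal2))`: the log2 ratio of
#' modal-standardized coverages. Both means are floored at `floor` so the
#' score is finite for all inputs (a germline-restricted repeat has zero
#' somatic coverage).
#'
#' @param mean1,mean2 mean depths of the interval in sample 1 / sample 2.
#' @param modal1,modal2 modal (single-copy) depths of the two samples.
#' @param floor depth floor applied to both means before standardization.
#' @return numeric score in log2 units; vectorized.
#' @export
enrichment_score <- function(mean1, mean2, modal1, modal2, floor = 1) {
  if (any(modal1 <= 0) || any(modal2 <= 0))
    stop("modal depths must be positive")
  log2((pmax(mean1, floor) / modal1) / (pmax(mean2, floor) / modal2))
}

#' Estimated genomic span of a repeat
#'
#' `sequence_length * (mean_depth / modal_depth)`: the total genome-wide
#' extent implied by the excess coverage over a single-copy locus (study
#' formula, with modal sperm coverage 73 as the published standard).
#'
#' @param sequence_length length in bp over which `mean_depth` was measured.
#' @param mean_depth mean sample-1 depth over that length.
#' @param modal_depth modal (single-copy) depth of sample 1.
#' @return span in bp; vectorized.
#' @export
estimate_span <- function(sequence_length, mean_depth, modal_depth) {
  if (any(modal_depth <= 0)) stop("modal depth must be positive")
  sequence_length * (mean_depth / modal_depth)
}

#' Germline filter parameters
#'
#' @param min_score minimum enrichment score (exclusive; study value 5).
#' @param min_span minimum estimated span in bp (exclusive; study value
#'   40,000).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_score = 5, min_span = 40000) {
  stopifnot(min_score > 0, min_span > 0)
  structure(list(min_score = min_score, min_span = min_span),
            class = "filter_params")
}

#' Filter intervals to germline-specific candidates
#'
#' Keeps intervals with `enrichment_score > min_score` and
#' `estimated_span > min_span` (both strictly greater); input order is
#' preserved.
#'
#' @param intervals data.frame with `enrichment_score` and `estimated_span`
#'   columns (see [score_intervals()]).
#' @param params a [filter_params()].
#' @return the qualifying rows.
#' @export
filter_germline <- function(intervals, params = filter_params()) {
  keep <- intervals$enrichment_score > params$min_score &
    intervals$estimated_span > params$min_span
  out <- intervals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach enrichment scores and spans to scanned intervals
#'
#' The somatic floor is the depth equivalent of a single copy of the
#' sequence's core unit (`modal2 * unit_length / eligible_bases`), so that
#' a family absent from the soma scores `log2(estimated germline unit
#' copies)` -- directly comparable to planted copy numbers. Setting
#' `floor_mode = "depth_unit"` floors at one read-depth unit instead.
#'
#' @param intervals output of [scan_intervals()].
#' @param modal1,modal2 modal depths of samples 1 and 2.
#' @param unit_lengths named vector of core unit lengths per sequence id
#'   (from [prepare_mapping_reference()]); defaults to the eligible length
#'   (floor of one whole-sequence copy) when missing.
#' @param floor_mode "unit_copy" (default) or "depth_unit".
#' @return `intervals` with `enrichment_score`, `estimated_span`,
#'   `unit_length` columns added.
#' @export
score_intervals <- function(intervals, modal1, modal2, unit_lengths = NULL,
                            floor_mode = c("unit_copy", "depth_unit")) {
  floor_mode <- match.arg(floor_mode)
  n <- nrow(intervals)
  u <- if (is.null(unit_lengths)) rep(NA_real_, n)
  else as.numeric(unit_lengths[intervals$sequence_id])
  u[is.na(u)] <- intervals$eligible_bases[is.na(u)]
  fl <- if (floor_mode == "unit_copy") {
    modal2 * u / intervals$eligible_bases
  } else {
    rep(1, n)
  }
  intervals$unit_length <- u
  intervals$enrichment_score <- enrichment_score(
    intervals$mean_depth_1, intervals$mean_depth_2, modal1, modal2, floor = fl)
  intervals$estimated_span <- estimate_span(
    intervals$eligible_bases, intervals$mean_depth_1, modal1)
  intervals
}
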