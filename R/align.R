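# Seeded local alignment wrapper (both strands) and alignment-derived
# library operations: reference merge and known-repeat exclusion.

#' Alignment and merge parameters
#'
#' Defaults follow the study's merge rules: de novo sequences aligning to a
#' reference repeat with >90% identity over 80% of their length are replaced
#' by the longer reference sequence; sequences matching a known repeat at
#' 99% identity are excluded; seeding uses exact 11-mer words.
#'
#' @param replace_identity minimum identity for reference replacement.
#' @param replace_coverage minimum fraction of the de novo sequence covered.
#' @param known_identity identity at/above which a sequence matching a known
#'   repeat is excluded.
#' @param seed_word_size exact-match seed length.
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @param band_extra half-width added around the seed diagonal band.
#' @param max_seed_gap maximum gap between chained seeds on a diagonal.
#' @param min_score minimum alignment score for a reported hit.
#' @param min_known_hit_columns minimum alignment columns for a hit to count
#'   toward known-repeat exclusion (guards against bare seed matches, which
#'   have identity 1 over a handful of columns).
#' @param max_word_occ cap on subject positions per seed word (0 = no cap).
#' @param max_clusters cap on seed clusters extended per sequence pair.
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(replace_identity = 0.90, replace_coverage = 0.80,
                         known_identity = 0.99, seed_word_size = 11L,
                         match = 1, mismatch = -2, gap_open = -5,
                         gap_extend = -2, band_extra = 16L,
                         max_seed_gap = 200L, min_score = 18,
                         min_known_hit_columns = 50L,
                         max_word_occ = 2000L, max_clusters = 20000L) {
  stopifnot(replace_identity > 0, replace_identity <= 1,
            replace_coverage > 0, replace_coverage <= 1,
            known_identity > 0, known_identity <= 1)
  structure(list(replace_identity = replace_identity,
                 replace_coverage = replace_coverage,
                 known_identity = known_identity,
                 seed_word_size = as.integer(seed_word_size),
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, band_extra = as.integer(band_extra),
                 max_seed_gap = as.integer(max_seed_gap),
                 min_score = min_score,
                 min_known_hit_columns = as.integer(min_known_hit_columns),
                 max_word_occ = as.integer(max_word_occ),
                 max_clusters = as.integer(max_clusters)),
            class = "merge_params")
}

#' Seeded local alignment of two sequences
#'
#' Finds exact `seed_word_size` matches on both strands, chains seeds by
#' diagonal, extends each chain by banded affine-gap local alignment, and
#' merges overlapping extensions. Identity is matches / alignment columns
#' (gap columns count). Coordinates are 0-based half-open on the forward
#' strand of each sequence; for minus-strand hits the query interval refers
#' to the original (un-complemented) query.
#'
#' @param query,subject DNA strings.
#' @param params a [merge_params()].
#' @param both_strands also align the reverse-complemented query.
#' @return data.frame of hits: `qstart`, `qend`, `sstart`, `send`, `strand`,
#'   `identity`, `aligned_query_fraction`, `score`, `matches`, `columns`,
#'   sorted by score descending.
#' @export
local_align <- function(query, subject, params = merge_params(),
                        both_strands = TRUE) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  run <- function(q) {
    cpp_local_align(q, subject, params$seed_word_size, params$match,
                    params$mismatch, params$gap_open, params$gap_extend,
                    params$band_extra, params$max_seed_gap, params$min_score,
                    params$max_word_occ, params$max_clusters)
  }
  qlen <- nchar(query)
  fwd <- run(query)
  fwd$strand <- rep("+", nrow(fwd))
  hits <- fwd
  if (both_strands) {
    rev <- run(revcomp(query))
    if (nrow(rev)) {
      qs <- qlen - rev$qend
      qe <- qlen - rev$qstart
      rev$qstart <- qs
      rev$qend <- qe
      rev$strand <- "-"
      hits <- rbind(hits, rev)
    }
  }
  if (!nrow(hits)) {
    hits$identity <- numeric(0)
    hits$aligned_query_fraction <- numeric(0)
    return(hits)
  }
  hits$identity <- hits$matches / hits$columns
  hits$aligned_query_fraction <- (hits$qend - hits$qstart) / qlen
  hits <- hits[order(-hits$score, hits$qstart, hits$sstart), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Batch local alignment of every query against every subject
#'
#' Same seeding/extension as [local_align()], but the subject word index is
#' built once per subject and all pairs are processed in compiled code. Per
#' pair with at least one hit, the best-scoring hit is reported together
#' with the maximum identity among hits spanning at least `min_cols`
#' alignment columns (`best_identity_min_cols`) and the count of such hits
#' (`n_hits_min_cols`). Cyclic subjects are doubled so rotations can match;
#' subject coverage is capped at the original length.
#'
#' @param queries,subjects character vectors of DNA sequences.
#' @param params a [merge_params()].
#' @param min_cols column threshold for the summary statistics.
#' @param subject_cyclic logical vector flagging cyclic subjects.
#' @return data.frame with one row per pair with hits: `query`, `subject`
#'   (1-based indices), best-hit coordinates/strand/score, `identity`,
#'   `aligned_query_fraction`, `aligned_subject_fraction`,
#'   `best_identity_min_cols`, `n_hits_min_cols`.
#' @export
align_pairs <- function(queries, subjects, params = merge_params(),
                        min_cols = 1L, subject_cyclic = NULL) {
  if (!length(queries) || !length(subjects)) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  subj_eff <- subjects
  if (!is.null(subject_cyclic) && any(subject_cyclic)) {
    subj_eff[subject_cyclic] <- paste0(subjects[subject_cyclic],
                                       subjects[subject_cyclic])
  }
  df <- cpp_align_pairs(queries, subj_eff, params$seed_word_size,
                        params$match, params$mismatch, params$gap_open,
                        params$gap_extend, params$band_extra,
                        params$max_seed_gap, params$min_score,
                        params$max_word_occ, params$max_clusters,
                        as.integer(min_cols))
  if (!nrow(df)) return(df)
  df$identity <- df$matches / df$columns
  qlen <- nchar(queries)[df$query]
  slen <- nchar(subjects)[df$subject]
  df$aligned_query_fraction <- (df$qend - df$qstart) / qlen
  df$aligned_subject_fraction <- pmin((df$send - df$sstart) / slen, 1)
  df$strand <- ifelse(df$strand == 1L, "-", "+")
  df
}

# Best qualifying hit of query against subject; cyclic subjects are doubled
# so rotations can match, with subject coverage capped at the original
# length. Returns NULL when there is no hit.
best_hit <- function(query, subject, params, subject_cyclic = FALSE) {
  slen <- nchar(subject)
  subj <- if (subject_cyclic) paste0(subject, subject) else subject
  h <- local_align(query, subj, params)
  if (!nrow(h)) return(NULL)
  h$aligned_subject_fraction <- pmin((h$send - h$sstart) / slen, 1)
  h[1L, , drop = FALSE]
}

assert_library <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  if (anyDuplicated(x$id)) stop("duplicate sequence ids in library")
  if (!"provenance" %in% names(x)) x$provenance <- "denovo"
  if (!"is_cyclic" %in% names(x)) x$is_cyclic <- FALSE
  if (!"unit_length" %in% names(x)) x$unit_length <- NA_integer_
  x
}

#' Merge a de novo library with a reference repeat library
#'
#' Each de novo sequence with a hit to a reference repeat at identity above
#' `replace_identity` covering more than `replace_coverage` of the de novo
#' sequence's length is replaced by the reference sequence when the
#' reference is longer. Replacements are de-duplicated; unmatched sequences
#' from both libraries pass through with provenance preserved.
#'
#' @param denovo,reference `repeat_library` data.frames (columns `id`,
#'   `sequence`; optional `provenance`, `is_cyclic`, `unit_length`).
#' @param params a [merge_params()].
#' @return merged `repeat_library` data.frame.
#' @export
merge_with_reference <- function(denovo, reference, params = merge_params()) {
  denovo <- assert_library(denovo)
  if (is.null(reference) || nrow(reference) == 0) return(denovo)
  reference <- assert_library(reference)
  reference$provenance <- "reference"
  if (any(denovo$id %in% reference$id))
    stop("duplicate ids across de novo and reference libraries")
  replacement <- rep(NA_character_, nrow(denovo))
  pairs <- align_pairs(denovo$sequence, reference$sequence, params,
                       subject_cyclic = reference$is_cyclic)
  if (nrow(pairs)) {
    qlen <- nchar(denovo$sequence)[pairs$query]
    slen <- nchar(reference$sequence)[pairs$subject]
    ok <- pairs$identity > params$replace_identity &
      pairs$aligned_query_fraction > params$replace_coverage &
      slen > qlen
    pairs <- pairs[ok, , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- pairs[order(-pairs$score, pairs$subject), , drop = FALSE]
      best <- pairs[!duplicated(pairs$query), , drop = FALSE]
      replacement[best$query] <- reference$id[best$subject]
    }
  }
  kept <- denovo[is.na(replacement), , drop = FALSE]
  used_ref <- unique(replacement[!is.na(replacement)])
  out <- rbind(kept[, c("id", "sequence", "provenance", "is_cyclic", "unit_length")],
               reference[, c("id", "sequence", "provenance", "is_cyclic", "unit_length")])
  out <- out[!duplicated(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replaced") <- data.frame(
    denovo_id = denovo$id[!is.na(replacement)],
    reference_id = replacement[!is.na(replacement)],
    stringsAsFactors = FALSE)
  attr(out, "replacement_refs") <- used_ref
  class(out) <- unique(c("repeat_library", class(out)))
  out
}

#' Exclude library sequences matching a known repeat
#'
#' Removes library sequences with any local hit to a known repeat at
#' identity at/above `identity_threshold` spanning at least
#' `min_known_hit_columns` alignment columns, then appends the known
#' sequences themselves once.
#'
#' @param library a `repeat_library` data.frame.
#' @param known data.frame of known repeats (`id`, `sequence`), or NULL.
#' @param params a [merge_params()]; `known_identity` and
#'   `min_known_hit_columns` control exclusion.
#' @return filtered library with the known sequences appended (provenance
#'   "known"); attribute `excluded` lists removed ids.
#' @export
exclude_known <- function(library, known, params = merge_params()) {
  library <- assert_library(library)
  if (is.null(known) || nrow(known) == 0) return(library)
  known <- assert_library(known)
  known$provenance <- "known"
  excluded <- logical(nrow(library))
  pairs <- align_pairs(library$sequence, known$sequence, params,
                       min_cols = params$min_known_hit_columns,
                       subject_cyclic = known$is_cyclic)
  if (nrow(pairs)) {
    hit <- pairs$best_identity_min_cols >= params$known_identity &
      pairs$n_hits_min_cols > 0L
    excluded[unique(pairs$query[hit])] <- TRUE
  }
  cols <- c("id", "sequence", "provenance", "is_cyclic", "unit_length")
  out <- rbind(library[!excluded, cols, drop = FALSE], known[, cols, drop = FALSE])
  out <- out[!duplicated(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- library$id[excluded]
  class(out) <- unique(c("repeat_library", class(out)))
  out
}
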