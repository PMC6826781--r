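# Greedy identity clustering of candidate repeats into families, plus
# cross-alignment cluster merging and the family report.

#' Clustering parameters
#'
#' Defaults follow the study's greedy clustering settings: 80% identity with
#' the alignment covering at least 30% of both the shorter and the longer
#' sequence, 11-mer seeds, and cluster pairs merged when linked by at least
#' four cross-alignment hits.
#'
#' @param identity_threshold minimum identity to join a cluster.
#' @param aS,aL minimum alignment coverage of the shorter / longer sequence.
#' @param merge_min_hits minimum cross-alignment hits to merge two clusters.
#' @param min_hit_len minimum alignment columns for a cross hit to count.
#' @param best_fit join the best-identity qualifying representative instead
#'   of the first (greedy first-fit is the default).
#' @param align a [merge_params()] providing seed/score settings.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.80, aS = 0.30, aL = 0.30,
                           merge_min_hits = 4L, min_hit_len = 50L,
                           best_fit = FALSE, align = merge_params()) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            aS > 0, aS <= 1, aL > 0, aL <= 1, merge_min_hits >= 1)
  structure(list(identity_threshold = identity_threshold, aS = aS, aL = aL,
                 merge_min_hits = merge_min_hits,
                 min_hit_len = as.integer(min_hit_len),
                 best_fit = best_fit, align = align),
            class = "cluster_params")
}

# Does query join the cluster of rep? Returns the qualifying identity or NA.
join_identity <- function(query, rep_seq, params, rep_cyclic = FALSE) {
  h <- best_hit(query, rep_seq, params$align, subject_cyclic = rep_cyclic)
  if (is.null(h)) return(NA_real_)
  qlen <- nchar(query); rlen <- nchar(rep_seq)
  cov_q <- h$aligned_query_fraction
  cov_s <- h$aligned_subject_fraction
  cov_short <- if (qlen <= rlen) cov_q else cov_s
  cov_long <- if (qlen <= rlen) cov_s else cov_q
  if (h$identity >= params$identity_threshold &&
      cov_short >= params$aS && cov_long >= params$aL) h$identity else NA_real_
}

#' Greedy identity clustering of a repeat library
#'
#' Sequences are processed longest-first; each is aligned (both strands)
#' against existing cluster representatives and joins the first cluster
#' whose representative it matches at `identity_threshold` with coverage of
#' at least `aS` of the shorter and `aL` of the longer sequence; otherwise
#' it founds a new cluster. The founder (longest member) is the
#' representative.
#'
#' @param library a `repeat_library` data.frame (unique ids).
#' @param params a [cluster_params()].
#' @return object of class `repeat_clusters`: list of clusters, each with
#'   `cluster_id`, `representative_id`, `member_ids`.
#' @export
greedy_cluster <- function(library, params = cluster_params()) {
  library <- assert_library(library)
  ord <- order(-nchar(library$sequence), library$id)
  lib <- library[ord, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(lib))) {
    q <- lib$sequence[i]
    joined <- FALSE
    best_id <- NA_real_; best_c <- 0L
    for (ci in seq_along(clusters)) {
      rep_row <- clusters[[ci]]$rep_row
      idn <- join_identity(q, rep_row$sequence, params,
                           rep_cyclic = isTRUE(rep_row$is_cyclic))
      if (!is.na(idn)) {
        if (!params$best_fit) {
          clusters[[ci]]$member_ids <- c(clusters[[ci]]$member_ids, lib$id[i])
          joined <- TRUE
          break
        } else if (idn > best_id || is.na(best_id)) {
          best_id <- idn; best_c <- ci
        }
      }
    }
    if (params$best_fit && best_c > 0L) {
      clusters[[best_c]]$member_ids <- c(clusters[[best_c]]$member_ids, lib$id[i])
      joined <- TRUE
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <- list(
        rep_row = lib[i, , drop = FALSE],
        representative_id = lib$id[i],
        member_ids = lib$id[i])
    }
  }
  out <- lapply(seq_along(clusters), function(ci) {
    list(cluster_id = sprintf("cluster_%03d", ci),
         representative_id = clusters[[ci]]$representative_id,
         member_ids = clusters[[ci]]$member_ids)
  })
  structure(out, class = "repeat_clusters")
}

#' @export
print.repeat_clusters <- function(x, ...) {
  cat(sprintf("repeat_clusters: %d clusters, %d members\n", length(x),
              sum(lengths(lapply(x, `[[`, "member_ids")))))
  invisible(x)
}

#' Membership table of a clustering
#' @param clusters a `repeat_clusters` object.
#' @return data.frame `cluster_id`, `member_id`, `is_representative`.
#' @export
cluster_membership <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, member_id = cl$member_ids,
               is_representative = cl$member_ids == cl$representative_id,
               stringsAsFactors = FALSE)
  }))
}

# Hit-count matrix between all member sequences: entry (a, b) is the number
# of local hits of at least min_hit_len alignment columns.
cross_hit_matrix <- function(library, params) {
  ap <- align_pairs(library$sequence, library$sequence, params$align,
                    min_cols = params$min_hit_len,
                    subject_cyclic = library$is_cyclic)
  m <- matrix(0L, nrow(library), nrow(library),
              dimnames = list(library$id, library$id))
  if (nrow(ap)) m[cbind(ap$query, ap$subject)] <- ap$n_hits_min_cols
  m
}

#' Merge clusters linked by cross-alignment hits
#'
#' Counts local-alignment hits (of at least `min_hit_len` columns) between
#' members of every cluster pair; pairs with at least `merge_min_hits` hits
#' are connected and connected components are merged (union-find). The
#' representative of a merged cluster is its longest member.
#'
#' @param clusters a `repeat_clusters` object.
#' @param library the `repeat_library` the clusters were built from.
#' @param params a [cluster_params()].
#' @return a `repeat_clusters` object; attribute `pair_hits` records the
#'   per-pair hit counts.
#' @export
cross_merge <- function(clusters, library, params = cluster_params()) {
  library <- assert_library(library)
  n <- length(clusters)
  if (n <= 1L) return(clusters)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  hm <- cross_hit_matrix(library, params)
  pair_rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      hits <- sum(hm[clusters[[i]]$member_ids, clusters[[j]]$member_ids])
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        cluster_a = clusters[[i]]$cluster_id,
        cluster_b = clusters[[j]]$cluster_id,
        hits = hits, merged = is.finite(params$merge_min_hits) &&
          hits >= params$merge_min_hits,
        stringsAsFactors = FALSE)
      if (is.finite(params$merge_min_hits) && hits >= params$merge_min_hits) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  lens <- nchar(library$sequence)
  names(lens) <- library$id
  out <- lapply(seq_along(groups), function(gi) {
    members <- unlist(lapply(clusters[groups[[gi]]], `[[`, "member_ids"),
                      use.names = FALSE)
    rep_id <- members[order(-lens[members], members)][1L]
    list(cluster_id = sprintf("cluster_%03d", gi),
         representative_id = rep_id, member_ids = members)
  })
  structure(out, class = "repeat_clusters",
            pair_hits = if (length(pair_rows)) do.call(rbind, pair_rows))
}

#' Cluster report: representatives, sizes and combined spans
#'
#' @param clusters a `repeat_clusters` object.
#' @param spans named numeric vector of estimated spans per member id.
#' @return data.frame `cluster_id`, `representative_id`, `n_members`,
#'   `combined_span`, `singleton`, ordered by combined span descending.
#' @export
cluster_report <- function(clusters, spans) {
  rows <- lapply(clusters, function(cl) {
    sp <- spans[cl$member_ids]
    sp[is.na(sp)] <- 0
    data.frame(cluster_id = cl$cluster_id,
               representative_id = cl$representative_id,
               n_members = length(cl$member_ids),
               combined_span = sum(sp),
               singleton = length(cl$member_ids) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$combined_span, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
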