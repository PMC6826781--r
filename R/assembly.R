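# De novo repeat assembly: a bidirected de Bruijn graph over canonical
# node-k-mers (node_k = 29 against abundant 31-mers), compacted into
# maximal non-branching consensus sequences. Tandem satellites appear as
# pure cycles and are linearized once with node_k - 1 wraparound bases.

flip_orient <- function(o) {
  if (length(o) == 1L) (if (o == "+") "-" else "+")
  else ifelse(o == "+", "-", "+")
}

#' Build a bidirected de Bruijn graph from abundant k-mers
#'
#' Nodes are the canonical `node_k`-mers occurring as windows of the input
#' k-mers; a directed edge joins two node orientations whenever they overlap
#' by `node_k - 1` bases. Because nodes are canonical, each edge carries the
#' orientations of both endpoints (bidirected graph).
#'
#' @param kmers character vector of (abundant) k-mers, all the same odd
#'   length greater than `node_k`.
#' @param node_k odd node size (study value 29).
#' @return an object of class `debruijn_graph`.
#' @export
build_graph <- function(kmers, node_k = 29L) {
  node_k <- as.integer(node_k)
  if (node_k %% 2L == 0L) stop("node_k must be odd")
  if (length(kmers) == 0) {
    return(structure(list(node_k = node_k, nodes = character(0),
                          succ_plus = NULL, succ_minus = NULL),
                     class = "debruijn_graph"))
  }
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("input k-mers must all have the same length")
  if (k %% 2L == 0L) stop("input k must be odd")
  if (node_k >= k) stop("node_k must be smaller than the input k-mer size")
  kmers <- toupper(kmers)
  windows <- unlist(lapply(seq_len(k - node_k + 1L), function(off) {
    substr(kmers, off, off + node_k - 1L)
  }), use.names = FALSE)
  nodes <- sort(unique(canonical_kmer(windows)))
  n <- length(nodes)
  rc <- revcomp(nodes)
  make_succ <- function(oriented) {
    sfx <- substr(oriented, 2L, node_k)
    m <- matrix(NA_integer_, nrow = n, ncol = 4L,
                dimnames = list(NULL, DNA_BASES))
    for (b in DNA_BASES) {
      cand <- paste0(sfx, b)
      canon <- canonical_kmer(cand)
      idx <- match(canon, nodes)
      sgn <- ifelse(cand == canon, 1L, -1L)
      m[, b] <- ifelse(is.na(idx), NA_integer_, idx * sgn)
    }
    m
  }
  structure(list(node_k = node_k, nodes = nodes,
                 succ_plus = make_succ(nodes), succ_minus = make_succ(rc)),
            class = "debruijn_graph")
}

#' Edge table of a de Bruijn graph
#'
#' Each bidirected edge is reported once (its mirror image under reverse
#' complement is suppressed).
#'
#' @param graph a `debruijn_graph`.
#' @return data.frame with columns `from`, `from_orient`, `to`, `to_orient`.
#' @export
graph_edges <- function(graph) {
  n <- length(graph$nodes)
  rows <- list()
  seen <- new.env(parent = emptyenv())
  for (o in c("+", "-")) {
    m <- if (o == "+") graph$succ_plus else graph$succ_minus
    if (is.null(m)) next
    for (v in seq_len(n)) {
      for (b in seq_len(4L)) {
        w <- m[v, b]
        if (is.na(w)) next
        ow <- if (w > 0L) "+" else "-"
        w <- abs(w)
        k1 <- paste(v, o, w, ow)
        k2 <- paste(w, flip_orient(ow), v, flip_orient(o))
        key <- min(k1, k2)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          from = graph$nodes[v], from_orient = o,
          to = graph$nodes[w], to_orient = ow, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(from = character(0), from_orient = character(0),
                      to = character(0), to_orient = character(0)))
  do.call(rbind, rows)
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("debruijn_graph: node_k=%d, %d nodes\n",
              x$node_k, length(x$nodes)))
  invisible(x)
}

# Successor entries of (v, o) as parallel vectors (hot path: no data.frame).
node_succ <- function(graph, v, o) {
  m <- if (o == "+") graph$succ_plus else graph$succ_minus
  row <- m[v, ]
  row <- row[!is.na(row)]
  if (!length(row)) return(NULL)
  list(idx = abs(unname(row)), orient = ifelse(row > 0L, "+", "-"),
       n = length(row))
}

oriented_seq <- function(graph, idx, orient) {
  s <- graph$nodes[idx]
  ifelse(orient == "+", s, revcomp(s))
}

# Consensus string of a node path (successive nodes overlap by node_k - 1).
path_consensus <- function(graph, idx, orient) {
  seqs <- oriented_seq(graph, idx, orient)
  if (length(seqs) == 1L) return(seqs)
  paste0(seqs[1L], paste(substr(seqs[-1L], graph$node_k, graph$node_k),
                         collapse = ""))
}

#' Compact a de Bruijn graph into repeat consensus sequences
#'
#' Maximal non-branching paths (every internal node has exactly one neighbor
#' on each side) are compressed into linear consensus sequences; boundary
#' (branching) nodes terminate paths and are shared by the unitigs meeting
#' there. Components that are pure cycles -- the signature of a tandem
#' repeat unit -- are linearized once, cut at the lexicographically smallest
#' node, emitted with `node_k - 1` wraparound bases, and flagged cyclic.
#' Linear outputs shorter than `min_length` are dropped (and logged in the
#' `dropped` attribute); cyclic outputs are kept regardless when
#' `keep_cyclic` is set, since short tandem cores are legitimate products.
#'
#' @param graph a `debruijn_graph` from [build_graph()].
#' @param min_length minimum linear consensus length in bp.
#' @param keep_cyclic keep cyclic consensi regardless of `min_length`.
#' @return a `repeat_library` data.frame with columns `id`, `sequence`,
#'   `provenance` ("denovo"), `is_cyclic`, `unit_length` (cycle period, NA
#'   for linear), `member_kmer_count`; ordered by length descending then
#'   sequence. Attribute `dropped` holds the dropped short outputs,
#'   attribute `n_branch_nodes` the branching-node count.
#' @export
assemble_unitigs <- function(graph, min_length = 58L, keep_cyclic = TRUE) {
  n <- length(graph$nodes)
  empty <- data.frame(id = character(0), sequence = character(0),
                      provenance = character(0), is_cyclic = logical(0),
                      unit_length = integer(0), member_kmer_count = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(structure(empty, class = c("repeat_library", "data.frame")))
  outdeg_p <- rowSums(!is.na(graph$succ_plus))
  outdeg_m <- rowSums(!is.na(graph$succ_minus))
  simple <- outdeg_p == 1L & outdeg_m == 1L
  used <- new.env(parent = emptyenv())
  edge_key <- function(v, o, w, ow) {
    min(paste(v, o, w, ow), paste(w, flip_orient(ow), v, flip_orient(o)))
  }
  contigs <- list()
  emit <- function(seq, cyclic, unit_len, nk) {
    contigs[[length(contigs) + 1L]] <<- list(sequence = seq, is_cyclic = cyclic,
                                             unit_length = unit_len,
                                             member_kmer_count = nk)
  }
  # isolated nodes
  for (v in which(outdeg_p == 0L & outdeg_m == 0L))
    emit(graph$nodes[v], FALSE, NA_integer_, 1L)
  # walks starting at branching (non-simple) nodes
  walk_from <- function(v, o, w, ow) {
    idx <- c(v, w); ori <- c(o, ow)
    repeat {
      tip <- idx[length(idx)]; to <- ori[length(ori)]
      if (!simple[tip]) break
      s <- node_succ(graph, tip, to)
      if (is.null(s) || s$n != 1L) break
      used[[edge_key(tip, to, s$idx, s$orient)]] <- TRUE
      idx <- c(idx, s$idx); ori <- c(ori, s$orient)
      if (s$idx == v && s$orient == o) break  # looped back to the start edge
      if (length(idx) > n + 1L) break         # safety
    }
    list(idx = idx, orient = ori)
  }
  for (v in which(!simple)) {
    for (o in c("+", "-")) {
      s <- node_succ(graph, v, o)
      if (is.null(s)) next
      for (j in seq_len(s$n)) {
        key <- edge_key(v, o, s$idx[j], s$orient[j])
        if (!is.null(used[[key]])) next
        used[[key]] <- TRUE
        p <- walk_from(v, o, s$idx[j], s$orient[j])
        seq <- path_consensus(graph, p$idx, p$orient)
        seq <- min(seq, revcomp(seq))
        emit(seq, FALSE, NA_integer_, length(p$idx))
      }
    }
  }
  # remaining components are pure cycles of simple nodes
  for (v in which(simple)) {
    s0 <- node_succ(graph, v, "+")
    if (is.null(s0)) next
    key0 <- edge_key(v, "+", s0$idx[1L], s0$orient[1L])
    if (!is.null(used[[key0]])) next
    idx <- v; ori <- "+"
    cur <- v; co <- "+"
    repeat {
      s <- node_succ(graph, cur, co)
      used[[edge_key(cur, co, s$idx[1L], s$orient[1L])]] <- TRUE
      cur <- s$idx[1L]; co <- s$orient[1L]
      if (cur == v) break
      idx <- c(idx, cur); ori <- c(ori, co)
      if (length(idx) > n) break  # safety
    }
    L <- length(idx)
    # cut at the lexicographically smallest node; orientation by smaller consensus
    cut <- which(graph$nodes[idx] == min(graph$nodes[idx]))[1L]
    rot <- function(i, o, at) {
      ord <- c(seq(at, length(i)), seq_len(at - 1L))
      list(idx = i[ord], orient = o[ord])
    }
    fwd <- rot(idx, ori, cut)
    rev_idx <- rev(idx); rev_ori <- flip_orient(rev(ori))
    rcut <- which(graph$nodes[rev_idx] == min(graph$nodes[rev_idx]))[1L]
    bwd <- rot(rev_idx, rev_ori, rcut)
    cyc_seq <- function(p) {
      u <- paste(substr(oriented_seq(graph, p$idx, p$orient), 1L, 1L),
                 collapse = "")
      reps <- ceiling((L + graph$node_k - 1L) / L)
      substr(strrep(u, reps + 1L), 1L, L + graph$node_k - 1L)
    }
    s1 <- cyc_seq(fwd); s2 <- cyc_seq(bwd)
    emit(min(s1, s2), TRUE, L, L)
  }
  if (!length(contigs)) return(structure(empty, class = c("repeat_library", "data.frame")))
  df <- data.frame(
    sequence = vapply(contigs, `[[`, "", "sequence"),
    is_cyclic = vapply(contigs, `[[`, TRUE, "is_cyclic"),
    unit_length = vapply(contigs, `[[`, 1L, "unit_length"),
    member_kmer_count = vapply(contigs, `[[`, 1L, "member_kmer_count"),
    stringsAsFactors = FALSE)
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  short <- !df$is_cyclic & nchar(df$sequence) < min_length
  if (keep_cyclic) {
    drop <- short
  } else {
    drop <- nchar(df$sequence) < min_length
  }
  dropped <- df[drop, , drop = FALSE]
  df <- df[!drop, , drop = FALSE]
  df <- df[order(-nchar(df$sequence), df$sequence), , drop = FALSE]
  out <- data.frame(id = sprintf("denovo_%05d", seq_len(nrow(df))),
                    sequence = df$sequence, provenance = "denovo",
                    is_cyclic = df$is_cyclic, unit_length = df$unit_length,
                    member_kmer_count = df$member_kmer_count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "n_branch_nodes") <- sum(!simple)
  class(out) <- c("repeat_library", class(out))
  out
}

#' Assemble a repeat library straight from abundant k-mers
#'
#' Convenience wrapper: [build_graph()] then [assemble_unitigs()].
#'
#' @inheritParams build_graph
#' @inheritParams assemble_unitigs
#' @return a `repeat_library` data.frame.
#' @export
assemble_repeats <- function(kmers, node_k = 29L, min_length = 58L,
                             keep_cyclic = TRUE) {
  assemble_unitigs(build_graph(kmers, node_k), min_length = min_length,
                   keep_cyclic = keep_cyclic)
}

#' Read a repeat library FASTA written by [write_library()]
#'
#' Parses provenance, cyclic flag and unit length back out of the headers;
#' plain FASTA files load with default metadata.
#'
#' @param path FASTA path.
#' @return a `repeat_library` data.frame.
#' @export
read_library <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(paste0(key, "="), hdr)] <- sub(paste0(key, "="), "", m)
    out
  }
  prov <- grab("provenance")
  cyc <- grab("is_cyclic")
  ul <- suppressWarnings(as.integer(grab("unit_length")))
  out <- data.frame(id = sub("\\s.*$", "", hdr),
                    sequence = as.character(x),
                    provenance = ifelse(is.na(prov), "denovo", prov),
                    is_cyclic = !is.na(cyc) & cyc == "TRUE",
                    unit_length = ul, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("repeat_library", class(out))
  out
}

#' Write a repeat library as FASTA
#'
#' Headers carry provenance, cyclic flag and unit length.
#'
#' @param library a `repeat_library` data.frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  seqs <- library$sequence
  names(seqs) <- sprintf("%s provenance=%s is_cyclic=%s unit_length=%s",
                         library$id, library$provenance,
                         library$is_cyclic, library$unit_length)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
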