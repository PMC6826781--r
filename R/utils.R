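# Shared small helpers: reverse complement, canonical k-mers, seeded RNG
# scopes, FASTA/FASTQ convenience wrappers.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized over a character vector; non-ACGT characters become N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(cpp_revcomp(x))
}

#' Canonical form of k-mers
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement, making counting strand-independent.
#'
#' @param x character vector of k-mers.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Random DNA string(s) of the given lengths (uses the current RNG stream).
random_dna <- function(lengths, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(lengths, function(n) {
    paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyNA(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# Write reads as Phred+33 FASTQ with a fixed quality character.
write_fastq <- function(reads, names, path, qual_char = "I") {
  quals <- strrep(qual_char, nchar(reads))
  lines <- as.vector(rbind(paste0("@", names), reads, "+", quals))
  con <- file(path, open = "wb")  # fixed newlines for byte-identical reruns
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# Read sequences from FASTQ file(s) into a character vector.
read_fastq_seqs <- function(paths) {
  unlist(lapply(paths, function(p) {
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  }), use.names = FALSE)
}

# Internal: coerce reads input (file paths or raw sequences) to a character
# vector of sequences. Paths are detected by file existence.
as_read_seqs <- function(reads) {
  if (length(reads) > 0 && all(file.exists(reads))) read_fastq_seqs(reads) else reads
}

`%||%` <- function(a, b) if (is.null(a)) b else a
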