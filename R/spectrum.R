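# Canonical k-mer spectra: streaming counts, modal copy number, abundance
# thresholding at a multiple of the mode.

new_kmer_spectrum <- function(ptr, k, source = NULL) {
  h <- cpp_spectrum_histogram(ptr)
  structure(list(
    k = k, ptr = ptr,
    histogram = data.frame(count = h$count, n_kmers = h$n_kmers),
    n_distinct = h$n_distinct, total_instances = h$total_instances,
    source = source
  ), class = "kmer_spectrum")
}

#' Count canonical k-mers in a read set
#'
#' Streams FASTQ/FASTA files (auto-detected) record by record; the read set
#' is never held in memory. Bases outside ACGT break the k-mer window; reads
#' shorter than k contribute nothing. Each k-mer is counted in its canonical
#' form (lexicographic minimum of the k-mer and its reverse complement);
#' odd k guarantees no k-mer is its own reverse complement.
#'
#' @param reads character vector of FASTQ/FASTA paths, or raw sequences.
#' @param k odd k-mer size between 3 and 31.
#' @return an object of class `kmer_spectrum` with the count histogram
#'   (`$histogram`: count -> number of distinct k-mers) and an internal
#'   count table queried by [abundant_kmers()] and [spectrum_kmer_counts()].
#' @export
count_kmers <- function(reads, k = 31L) {
  k <- as.integer(k)
  ptr <- cpp_spectrum_new(k)
  if (length(reads)) {
    if (all(file.exists(reads))) {
      for (f in reads) cpp_spectrum_add_file(ptr, f)
      src <- reads
    } else {
      cpp_spectrum_add_seqs(ptr, toupper(reads))
      src <- sprintf("<%d in-memory sequences>", length(reads))
    }
  } else src <- "<empty>"
  new_kmer_spectrum(ptr, k, source = src)
}

#' Build a spectrum from explicit k-mer counts
#'
#' Used to reload persisted spectra and to construct small test fixtures.
#' K-mers are canonicalized on entry; counts for a k-mer and its reverse
#' complement accumulate.
#'
#' @param kmers character vector of k-mers (equal length, ACGT only).
#' @param counts numeric vector of non-negative counts.
#' @param k k-mer size; defaults to the length of the first k-mer.
#' @return a `kmer_spectrum`.
#' @export
spectrum_from_counts <- function(kmers, counts, k = nchar(kmers[1])) {
  stopifnot(length(kmers) == length(counts))
  ptr <- cpp_spectrum_new(as.integer(k))
  if (length(kmers)) cpp_spectrum_add_counts(ptr, toupper(kmers), as.numeric(counts))
  new_kmer_spectrum(ptr, as.integer(k), source = "<explicit counts>")
}

#' All k-mer counts of a spectrum
#'
#' Materializes the full canonical k-mer -> count table; intended for small
#' spectra (tests, persisted output).
#'
#' @param spectrum a `kmer_spectrum`.
#' @param min_count only return k-mers with at least this count.
#' @return data.frame with columns `kmer`, `count`, ordered by k-mer.
#' @export
spectrum_kmer_counts <- function(spectrum, min_count = 1) {
  x <- cpp_spectrum_extract(spectrum$ptr, min_count)
  data.frame(kmer = x$kmer, count = x$count, stringsAsFactors = FALSE)
}

#' Modal copy number of a k-mer spectrum
#'
#' The count value with the largest number of distinct k-mers, after
#' excluding the low-count error peak (`counts < error_peak_min`). Ties are
#' broken toward the larger count.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param error_peak_min counts below this are ignored when locating the
#'   mode (real spectra have a sequencing-error peak at count 1-4).
#' @return integer modal copy number.
#' @export
modal_copy_number <- function(spectrum, error_peak_min = 5L) {
  h <- spectrum$histogram
  h <- h[h$count >= error_peak_min, , drop = FALSE]
  if (!nrow(h))
    stop("cannot estimate modal copy number: no k-mer counts >= ", error_peak_min)
  as.integer(max(h$count[h$n_kmers == max(h$n_kmers)]))
}

#' Abundance threshold for a spectrum
#'
#' @param spectrum a `kmer_spectrum`.
#' @param multiplier threshold multiple of the modal copy number (study
#'   value 3, giving thresholds 165 for sperm and 180 for blood reads).
#' @param error_peak_min passed to [modal_copy_number()].
#' @return numeric threshold `multiplier * modal_copy_number`.
#' @export
abundance_threshold <- function(spectrum, multiplier = 3, error_peak_min = 5L) {
  multiplier * modal_copy_number(spectrum, error_peak_min)
}

#' Extract abundant k-mers
#'
#' Returns all canonical k-mers whose count is at least (inclusive)
#' `multiplier` times the modal copy number.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param multiplier threshold multiple of the mode.
#' @param error_peak_min passed to [modal_copy_number()].
#' @param threshold explicit threshold overriding `multiplier * mode`.
#' @return character vector of canonical k-mers with attributes `threshold`,
#'   `mode` and `counts` (the per-k-mer counts, same order).
#' @export
abundant_kmers <- function(spectrum, multiplier = 3, error_peak_min = 5L,
                           threshold = NULL) {
  mode <- tryCatch(modal_copy_number(spectrum, error_peak_min),
                   error = function(e) if (is.null(threshold)) stop(e) else NA_integer_)
  if (is.null(threshold)) threshold <- multiplier * mode
  x <- cpp_spectrum_extract(spectrum$ptr, threshold)
  structure(as.character(x$kmer), threshold = threshold, mode = mode,
            counts = as.numeric(x$count))
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, %s distinct canonical k-mers, %s instances\n",
              x$k, format(x$n_distinct, big.mark = ","),
              format(x$total_instances, big.mark = ",")))
  invisible(x)
}

#' Persist a spectrum as TSV plus JSON sidecar
#'
#' Writes the full k-mer count table (TSV: kmer, count) and a JSON sidecar
#' recording k, modal copy number and threshold. Intended for thresholded or
#' small spectra.
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path TSV output path; the sidecar is `<path>.json`.
#' @param min_count only persist k-mers with at least this count.
#' @param ... passed to [modal_copy_number()]/[abundance_threshold()].
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, min_count = 1, ...) {
  tab <- spectrum_kmer_counts(spectrum, min_count)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = spectrum$k,
               modal_copy_number = tryCatch(modal_copy_number(spectrum, ...),
                                            error = function(e) NA),
               threshold = tryCatch(abundance_threshold(spectrum, ...),
                                    error = function(e) NA),
               n_distinct = spectrum$n_distinct,
               total_instances = spectrum$total_instances)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Reload a spectrum written by [write_spectrum()]
#' @param path TSV path.
#' @return a `kmer_spectrum`.
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  spectrum_from_counts(tab$kmer, tab$count)
}
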