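#!/usr/bin/env Rscript
# Stage 2: k-mer spectra, abundance thresholds, repeat assembly, library
# merge. Mirrors the study's front end: canonical 31-mers per tissue,
# abundance cut at 3x the modal copy number, de Bruijn assembly at node
# size 29, merge with the reference repeat models (>90% identity over 80%
# of length -> replaced by the longer model) and exclusion of sequences
# matching the known germline repeat at 99% identity.

suppressPackageStartupMessages(library(germsat))

data_dir <- "results/scenario"
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

reads_g <- file.path(data_dir, c("germline_R1.fastq", "germline_R2.fastq"))
reads_s <- file.path(data_dir, c("somatic_R1.fastq", "somatic_R2.fastq"))

sp_g <- count_kmers(reads_g, k = 31)
sp_s <- count_kmers(reads_s, k = 31)
ab_g <- abundant_kmers(sp_g, multiplier = 3)
ab_s <- abundant_kmers(sp_s, multiplier = 3)
thresholds <- data.frame(
  sample = c("germline", "somatic"),
  modal_copy_number = c(attr(ab_g, "mode"), attr(ab_s, "mode")),
  abundance_threshold = c(attr(ab_g, "threshold"), attr(ab_s, "threshold")),
  n_abundant_kmers = c(length(ab_g), length(ab_s)))
write.table(thresholds, file.path(out, "kmer_thresholds.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Abundance thresholds (3x modal copy number):\n")
print(thresholds, row.names = FALSE)

abundant <- sort(unique(c(as.character(ab_g), as.character(ab_s))))
cat("\nUnion of abundant 31-mers:", length(abundant), "\n")

denovo <- assemble_repeats(abundant, node_k = 29, min_length = 29)
cat("De novo consensus sequences:", nrow(denovo),
    "(", sum(denovo$is_cyclic), "cyclic tandem units;",
    "high within-family divergence shatters most cycles into fragments,",
    "as in real satellite assemblies)\n")

reference <- read_library(file.path(data_dir, "reference_repeats.fasta"))
known <- read_library(file.path(data_dir, "known_repeats.fasta"))
lib <- merge_with_reference(denovo, reference)
cat("Fragments replaced by longer reference models:",
    nrow(attr(lib, "replaced")), "->", length(attr(lib, "replacement_refs")),
    "distinct models\n")
lib <- exclude_known(lib, known)
cat("Excluded as matching the known germline repeat at 99%:",
    length(attr(lib, "excluded")), "(known sequence appended once)\n")
write_library(lib, file.path(out, "library.fasta"))
cat("Model repeat library:", nrow(lib), "sequences -> results/library.fasta\n")
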