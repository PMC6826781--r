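Package: germsat
Title: Discovery of Germline-Restricted Satellite Repeats from Two-Tissue Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative germline-versus-soma discovery of high-copy tandem
    repeats from short-read sequencing of two tissues. Counts canonical k-mers
    per read set and thresholds them at a multiple of the modal copy number,
    assembles the abundant k-mers into repeat consensus sequences on a
    bidirected de Bruijn graph, merges the de novo products with a
    reference-derived repeat library and a known-repeat set under explicit
    identity and coverage rules, scores germline enrichment of each library
    sequence as the log2 ratio of modal-standardized read coverages with an
    estimated genomic span, clusters the filtered candidates into repeat
    families by greedy identity clustering with cross-alignment merging, and
    annotates the tandem architecture (core unit period, inverted cassettes,
    best genomic scaffold) of each family. A synthetic genome and read
    generator plants shared and germline-restricted satellite families with a
    ground-truth table so the whole pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
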