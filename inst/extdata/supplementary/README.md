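# Supplementary reproduction inputs (not redistributed)

The published set of 171 germline-enriched repeat sequences is not
shipped with the package. To run the clustering reproduction in
`tests/testthat/test-acceptance.R`, download the study's supplementary
sequence set and place it here as:

    germline_enriched.fasta

with one record per element and the estimated genomic span recorded in
each header as `span=<bp>`. Greedy clustering at the default parameters
should then yield 30 clusters, 20 after cross-merge (8 multi-member,
12 singletons), with the top six representatives' combined span
exceeding 500 kb.
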