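# germsat — germline-restricted satellite repeat discovery

Some animals jettison part of their genome from somatic cells early in
development. The discarded, germline-restricted DNA is dominated by
high-copy satellite repeats: short core units (13–57 bp) repeated
head-to-tail over tens of kilobases, disrupted by small indels and
duplicated as inverted cassettes. `germsat` finds these elements from
shotgun sequencing of two tissues — one germline (e.g. sperm), one somatic
(e.g. blood) — without a complete genome assembly.

## Method

For each read set, canonical *k*-mers (*k* = 31) are counted and
thresholded at 3× the modal copy number; the abundant *k*-mers (union of
the two samples) are assembled into repeat consensus sequences on a
bidirected de Bruijn graph (node size 29), merged with a reference-derived
repeat library (>90% identity over 80% of length → replaced by the longer
model) and purged of sequences matching a known repeat at 99% identity.
Both read sets are then mapped back to the model library; per-base depths
are scanned into intervals (v = 5000, l = 0, a = b = 10, caps 12M) and
each interval is scored

```
enrichment = log2( (cov_germline / modal_germline) / (max(cov_soma, floor) / modal_soma) )
span       = length × cov_germline / modal_germline
```

where `modal_*` is the sample's modal (single-copy) depth. Intervals with
**score > 5 and span > 40 kb** are germline-specific candidates; they are
grouped into families by greedy identity clustering (0.8 identity, 0.3/0.3
coverage of shorter/longer; clusters with ≥ 4 cross-alignment hits merged)
and annotated with their tandem core unit, inverted cassettes, best
genomic scaffold, and a somatic-abundance ranking that nominates
centromeric satellite candidates.

A synthetic scenario generator plants shared and germline-restricted
satellite families into a genome pair with a full truth table, so every
stage is testable without external data.

## Worked example

```r
library(germsat)
run <- run_standard_scenario(seed = 1)
run$recovery$per_family[, c("family_id", "restricted", "detected",
                            "measured_score", "expected_score")]
```

```
        family_id restricted detected measured_score expected_score
     germfam1_u13       TRUE     TRUE          12.13          12.24
     germfam2_u21       TRUE     TRUE          11.47          11.55
     germfam3_u29       TRUE     TRUE          11.07          11.09
     germfam4_u37       TRUE     TRUE          10.74          10.73
     germfam5_u46       TRUE     TRUE          10.43          10.42
     germfam6_u57       TRUE     TRUE          10.09          10.11
  sharedfam1_u120      FALSE    FALSE           0.02           0.00
  sharedfam2_u150      FALSE    FALSE           0.02           0.00
  sharedfam3_u180      FALSE    FALSE           0.05           0.00
```

(Values shown for seed 101; seed 1 differs in the third decimal.) All six
planted germline-restricted families are detected with enrichment scores
matching `log2(copies)` to within ~0.1 log2 units and spans within ~8% of
the planted extents; the three shared pericentromeric families score ≈ 0
and never pass the filter. `run$result$cluster_table` lists one cluster
per family, ordered by combined span, and `run$result$somatic_ranking`
places the shared (centromere-like) families on top, mirroring how
somatically abundant repeats localize to centromeres.

The same analysis, stage by stage with intermediate tables under
`results/`, is in `analysis/01_simulate.R` … `analysis/05_evaluate.R`
(set `GERMSAT_SEED` to change the seed).

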