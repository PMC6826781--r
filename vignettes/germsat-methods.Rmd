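---
title: "Discovering germline-restricted satellite repeats from two-tissue sequencing"
author: "germsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering germline-restricted satellite repeats from two-tissue sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Some animals reproducibly discard parts of their genome from somatic cells
during early development (programmed genome rearrangement). The discarded,
germline-restricted fraction is rich in high-copy satellite DNA: short core
units (as short as 13 bp) repeated head-to-tail over tens of kilobases,
frequently disrupted by small indels and, at larger scales, duplicated as
inverted cassettes. `germsat` identifies such elements computationally by
comparing shotgun sequencing of a germline tissue (e.g. sperm) with a
somatic tissue (e.g. blood): an element present only in the germline shows
high read coverage in the germline sample and essentially none in the soma.

The pipeline has six computational stages, each exposed as ordinary R
functions and orchestrated by `run_pipeline()`:

1. **k-mer spectrum** — canonical 31-mer counts per read set;
   *abundant* k-mers are those with count at least 3x the modal copy
   number of the spectrum (the mode sits at the single-copy coverage, so
   the threshold adapts to sequencing depth per sample).
2. **repeat assembly** — abundant 31-mers (union over the two samples)
   are assembled on a bidirected de Bruijn graph with node size 29;
   maximal non-branching paths become consensus sequences and pure cycles
   — the signature of a clean tandem unit — are linearized once with
   `node_k - 1` wraparound bases.
3. **library merge** — de novo products aligning to a reference-derived
   repeat model at more than 90% identity over more than 80% of their
   length are replaced by the longer model (deduplicated); sequences
   matching a previously known germline repeat at 99% identity are
   excluded and the known sequence is appended once.
4. **coverage & enrichment** — both read sets are placed on the library
   (best seeded location per read); per-base depths are scanned into
   intervals (minimum 5000 eligible bases per interval, eligibility =
   depth at least 10 in either sample, caps at 12M); each interval gets an
   enrichment score `log2((mean1/modal1) / (max(mean2, floor)/modal2))`
   and an estimated genomic span `length x mean1 / modal1`; the germline
   filter keeps intervals with score strictly above 5 *and* span strictly
   above 40 kb.
5. **clustering** — filtered candidates are grouped into families by
   greedy incremental clustering (join at 80% identity when the alignment
   covers at least 30% of both the shorter and the longer sequence);
   cluster pairs linked by at least four cross-alignment hits are merged
   transitively.
6. **annotation** — per family: tandem core unit (periodicity analysis),
   inverted cassettes (self versus reverse-complement alignment), best
   genomic scaffold (count of 11-mer-seeded hits covering at least 80% of
   the repeat), and a ranking of repeats by *somatic* coverage, which
   nominates centromeric satellite candidates shared by all chromosomes.

```{r}
library(germsat)
run <- run_standard_scenario(seed = 1)
run$recovery$per_family
run$result$cluster_table
```

## The synthetic scenario: what it emulates, and what it does not

Real germline/soma read pairs with known ground truth do not exist, so the
package ships a generator (`standard_scenario()`, `build_genome_pair()`,
`simulate_reads()`) that plants satellite families with a full truth table.
The standard scenario fixes the study conditions at desk scale:

* two genomes of 2 Mb (two scaffolds each) sharing one random backbone;
* three **shared** pericentromeric satellite families (core units 120,
  150, 180 bp; about 50 kb planted in each genome, identical copies at
  identical coordinates in both genomes — the somatic genome is the
  germline genome minus the restricted material, as in programmed
  elimination);
* six **germline-restricted** families with core units 13, 21, 29, 37,
  46 and 57 bp — spanning the observed range of germline satellite core
  sizes — each planted over at least 60 kb, giving standardized copy
  ratios of 1100-4850 (well above the ratio of 64 the filter must
  resolve);
* within-family divergence of 3% substitutions per copy ("somewhat
  conserved" cores), 2% indel-disrupted unit junctions (1-3 bp), and
  inverted cassettes of 20 units at 10% probability;
* 40x coverage per tissue of 150 bp paired reads (fragment size
  400 +/- 30 bp) with a substitution-only error rate of 0.2% per base,
  a typical post-filter short-read error rate;
* a reference repeat library containing tiled unit models of all nine
  families plus two decoy models (a repeat annotator run on the germline
  reference assembly would recover germline-restricted satellites too,
  since the reference genome of the study species is germline-derived),
  and a "known repeat" — the first restricted family's unit — exercising
  the exclusion rule.

Coordinates are 0-based half-open, orientation is `+`/`-`, arrays replace
backbone spans of equal length, and one integer seed drives every stage
(scenario units, genome layout, mutations, read sampling) through fixed
offsets, so the whole pipeline is reproducible from a single number.

What the generator deliberately does **not** model: sequencing indel
errors, PCR duplicates, GC bias, quality-score structure, diploid
heterozygosity, or repeat families related to one another by partial
homology. Passing tests therefore demonstrate that the *method* measures
what it claims under controlled satellite architecture and substitution
noise; they do not certify performance on real libraries with coverage
biases, nor the behaviour of the funnel at real-genome scale (a 2 Mb
backbone produces thousands, not hundreds of thousands, of intervals).

## Why the high-copy cycles shatter, and why that is fine

A clean tandem unit yields a de Bruijn cycle. But at the planted copy
numbers (about 1100-4850 copies), even a 1% shared-variant rate puts many
*copy-shared* substitution variants above the abundance threshold: each
variant k-mer attaches to the cycle as a branch, and compaction cuts the
cycle into fragments. This is not an artifact of the generator — it is
exactly why real satellite assemblies produce hundreds of thousands of
short consensus fragments. The pipeline recovers families the way the
original analysis did: the reference-model merge step replaces fragments
(at >90% identity over >80% of their length) with full-length models, and
the coverage stage measures family abundance on those models. With the
merge step disabled (no reference library), families with units of 30 bp
or more still assemble as near-full-length fragments and survive; very
short, very-high-copy units degrade, which the methods here share with the
original toolchain.

Two related implementation choices follow:

* `assemble_unitigs()` defaults to a 58 bp floor on linear outputs, but
  the pipeline passes `min_contig_length = 29` (the node size): tandem
  cores of 13-57 bp produce fragments shorter than 58 bp, and they are
  the very objects under study. Cyclic outputs are kept at any length.
* Fragments that mix forward and inverted cassette sequence (junction
  contigs) are not replaced by any model (their alignment coverage per
  strand stays below 80%); they pass through, accumulate negligible span,
  and are removed by the span filter.

## Numerical and measurement choices

**Identity** is matches over alignment columns, with gap columns counted,
everywhere (merge, exclusion, clustering, annotation). Alignment scoring
defaults to +1/-2 with affine gaps -5/-2 and 11-mer seeds; extension is
banded Smith-Waterman around the seeded diagonals, which agrees exactly
with full dynamic programming on substitution-dominated inputs (checked
against `Biostrings::pairwiseAlignment` in the test suite).

**Read placement.** Reads are placed at their best seeded location
(19-mer seeds probed every 9 bases, both strands, top-voted diagonals
rescored ungapped); the best-scoring run on the winning diagonal is used
(match +1 / mismatch -2), so reads crossing an indel junction or an array
boundary are soft-clipped to their well-aligned part rather than lost.
Ties go to the lexicographically smallest reference id, then the leftmost
position, then the forward strand — deterministic, and consistent across
samples so coverage ratios are unbiased. Placements below 80% matches
over the aligned run are counted unplaced.

**Short tandem references are tiled before mapping.** A 13 bp core's
consensus is shorter than a read, and depth measured on it would
undercount by the ratio of lengths. Any library sequence shorter than
twice the read length whose tandem period is detectable is therefore
concatemerized from its core consensus to at least
`max(2 * read_length, read_length + 2 * period)` — the standard
satellite-mapping practice — and depths, intervals and spans are reported
on the tiled length, which cancels out of the span formula.

**Span** is computed per interval as
`eligible_length x mean_depth / modal_depth`. When the whole sequence is
eligible this is exactly the published sequence-length formula; defining
it on the eligible length keeps the estimate correct when placements
pile up on one phase of a periodic reference (total aligned bases are
conserved).

**The somatic floor.** A germline-restricted family has zero somatic
coverage, and the score must stay finite. The pipeline floors the somatic
mean at the depth equivalent of a *single copy of the core unit*
(`modal2 x unit_length / eligible_length`), so the score of a
soma-absent family reads directly as `log2(estimated germline unit
copies)` — the same scale as the truth table's expected
`log2(copies_germline / max(copies_somatic, 1))`. A plain one-read-depth
floor is available (`floor_mode = "depth_unit"`); it only changes the
(arbitrary) scale of soma-absent scores, not which intervals pass the
filter in practice.

**Modal (single-copy) depth** standardizes the two samples. When genomic
scaffolds are supplied, each read set is mapped to them and the modal
per-base depth (ties upward) is taken — the analogue of the study's
modal germline coverage of 73. Without scaffolds it falls back to the
k-mer-spectrum mode rescaled by `read_length / (read_length - k + 1)`.

**Interval estimator.** Interval means are ratio-of-means over eligible
(capped) bases; a mean-of-ratios alternative was considered and rejected
because per-base depth ratios are unstable at the eligibility boundary.

**Period detection** reports the *smallest* period with self-match
fraction at least 0.8 over the default range 5-200 bp (any multiple of
the true unit also qualifies; smallest-p is the convention). Random
sequence scores near 0.25 under every shift, so the 0.8 cut is
conservative. The column-majority consensus breaks ties toward the
alphabetically first base.

**Cluster semantics.** Greedy clustering is first-fit over
length-descending input (a best-fit switch exists); the representative is
the longest member. A cross-merge "hit" is a maximal merged local
alignment of at least 50 columns, counted per hit (not per sequence
pair); merging is transitive via union-find, never increases the cluster
count, and an infinite hit threshold is the identity.

**Degenerate inputs.** Empty read sets give empty spectra; an empty
abundant set gives an empty graph and library (not an error); a sequence
equal to its own reverse complement cannot occur at odd k; self-loop
nodes (sub-period units) terminate unitig walks rather than looping.

## Problem sizes and determinism

The packaged standard scenario (2 Mb per genome, 40x per tissue, about
1.07 million read pairs per sample) runs end-to-end in a few minutes on
one CPU; the test suite repeats it across five seeds for score/span
calibration and uses a 120 kb / 25x variant for orchestration tests.
These sizes were chosen so that single-copy coverage estimation, the
interval scan and the filter behave exactly as at genome scale while the
whole analysis stays interactive. Every stage is deterministic given the
input files: rerunning a configuration reproduces candidate tables
byte-for-byte, and `run_pipeline()` caches completed stages keyed by
their inputs, so an unchanged configuration resumes instead of
recomputing.

## Known limitations

* Enrichment is measured per library sequence; families whose fragments
  are split across several models (no reference model to merge onto)
  divide their span across entries and can fall below the span filter —
  shared with the original multi-tool pipeline, and visible in the
  recovery report as `split` correspondence.
* The read placer is substitution-oriented (clipped, ungapped rescoring);
  indel-rich *reads* (long-read data) would need a gapped mapper.
* Scaffold assignment counts alignment hits, which for tandem repeats
  scale with array length over unit length; counts are comparable across
  scaffolds but are not copy-number estimates.
* The 3x-modal abundance threshold assumes a visible single-copy mode in
  the k-mer spectrum; ultra-low coverage (below roughly 10x) or heavily
  contaminated libraries violate that assumption, and
  `modal_copy_number()` will refuse spectra with no mass above the error
  peak rather than guess.
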