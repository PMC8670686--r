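---
title: "Detecting crosslink-induced deletions in RNA sequencing reads"
author: "jumpdel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting crosslink-induced deletions in RNA sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpdel)
```

## The measurement

A bi-reactive SHAPE reagent (or a psoralen, or short-wavelength UV) covalently
bridges two ribose 2'-hydroxyl groups that sit close in space. An engineered
reverse transcriptase traverses the crosslink during cDNA synthesis, leaving a
deletion in the cDNA whose two boundary nucleotides — the last templated base
before the jump (the 3' site in RNA coordinates) and the first after it — mark
the crosslinked positions. Sequencing the cDNA library therefore converts
through-space proximity into deletion records. Two properties of the
crosslink-traversing enzyme complicate the readout: it mutates templated
nucleotides at roughly 3-4% per position (mismatches, single-base indels), and
its "landing" after a jump is imprecise by a couple of nucleotides.

`jumpdel` turns raw reads from such an experiment into a table of deletion
sites with depth-normalized, background-subtracted rates, and bundles the
simulation and structure-aware evaluation machinery needed to benchmark every
stage.

## Pipeline model

For each sample (crosslinked and mono-adduct control):

1. **Quality trimming** (`trim_reads()`): Phred scores are scanned 5' to 3'
   with a sliding 5-nt window; at the first window whose mean falls below 20
   the window and everything downstream are removed; reads shorter than 25 nt
   are dropped. The window slides in steps of one — the stricter reading of
   "first set of 5 nucleotides", and the behavior of the trimmer this rule
   mirrors.
2. **Pair merging** (`merge_reads()`): the mate is reverse-complemented and
   the overlap (≥ 10 nt) minimizing mismatch density (≤ 0.25 accepted, ties to
   the longer overlap) is merged; in the overlap the higher-quality base wins
   and its score is raised to `min(q1 + q2, 41)`. Non-overlapping pairs are
   kept unmerged, and merged/unmerged sets are aligned separately.
3. **Alignment**: BWA-MEM with scoring tuned for this read class — gap open
   `-O 2`, mismatch `-B 2`, seed `-k 10`, score threshold `-T 15`. Lower gap
   and mismatch penalties accommodate the RT error rate and long internal
   deletions; the short seed and low threshold let short flanks on either side
   of a junction anchor an alignment.
4. **Deletion detection** (`detect_deletions()`): described below.
5. **Quantification**: each deletion's count is divided by the median read
   depth over the five positions starting at its 3' site; control rates are
   subtracted (crosslink-only sites keep their full rate, non-positive net
   rates are dropped); finally 5' sites are shifted 2 nt in the 3' direction
   to compensate for the RT landing offset. The shift is applied after
   subtraction, matching the order in which the procedure is defined.

## Deletion detection

Deletions are parsed from CIGAR strings. Short deletions appear inline as `D`
ops; a maximal run of `D`/`I` ops whose deleted length reaches 10 nt forms one
candidate junction, with interleaved `I` bases counted as junction insertion.
Longer deletions split a read into two alignments; adjacent segments in query
order define a candidate whose deleted block is the intervening reference and
whose insertion is the unaligned query between them.

Two corrections give the method its single-nucleotide accuracy:

* **Ambiguous-deletion removal.** When the base at the 5' site equals the
  last deleted base (`ref[five] == ref[three - 1]`) or the first deleted base
  equals the base at the 3' site (`ref[five + 1] == ref[three]`), the deleted
  block can slide and the junction is not unique; the aligner places such
  junctions with a systematic directional bias. These records are removed.
  For contiguous blocks this two-sided single-slide test is equivalent to
  enumerating all placements (a property the test suite enforces against a
  brute-force oracle), so the check is O(1) per record.
* **Exact edge matching.** The three read bases aligned on each side of the
  junction must exactly match the reference. While any flank base mismatches,
  that boundary moves one nucleotide to the exterior and the displaced read
  base is reclassified as junction insertion; a junction needing more than 10
  total moves is dropped.

Filters apply in a fixed order: edge matching, ambiguity removal, removal of
junction insertions longer than 10 nt, then deduplication of identical
`(read, five, three)` records arising from mate overlap or merged/unmerged
double counting. Reverse-strand and secondary alignments are discarded with a
tally (the assay is amplicon-directional). The minimum-length rule is applied
both before and after edge shifting; shifting can only grow a deletion, so the
pre-filter is safe and cheaper.

### Overlapping split alignments

A practical complication the CIGAR stream does not announce: when a junction
is flanked by homologous sequence — or when short spurious blocks
chance-match past it — the aligner extends *both* segments of a split read
through the junction, so their query spans overlap. Raw junctions assign the
overlap to the upstream segment (the aligner aligns ambiguous bases before
the gap, so this matches its bias). With edge matching enabled, the split
point is re-derived exactly: every split position in the overlap window is
scored by the run of read-vs-reference matches along each segment's dominant
diagonal (longest aligned block), a valid split needs at least the 3-nt flank
on each side, and the best-supported split wins, ties to the most 3'-extended
placement. Sloppy chance-matching extensions break at their indels within a
few bases, so the true junction wins whenever the read contains it. This is
the edge-matching principle applied at split junctions and is what makes
noise-free reads recoverable exactly.

## The synthetic benchmark

`generate_dataset()` emulates the study conditions the detection method was
tuned under:

* full-length amplicon reads over a ~325-nt reference (the bundled
  `benchmark_reference()` is a fixed seeded-random stand-in with 14-nt 5' and
  43-nt 3' structure cassettes; any user FASTA is accepted);
* one encoded deletion per read, (5', 3') sites drawn uniformly over pairs
  with a gap of at least 10 nt and both sites outside the cassettes;
* in deletion-insertion mode, a random-nucleotide junction insertion with
  lengths 1-9 from a truncated geometric distribution (ratio 0.5) — the
  empirical insertion-length distribution is only available graphically, so
  this default is a declared, configurable substitute;
* RT-style noise: each position mutates independently at 3.75%; of the
  events, 71% are mismatches, 26% single-base deletions, 3% single-base
  insertions;
* constant Phred 38 qualities, so trimming is a no-op and the benchmark
  isolates aligner plus detector.

What the generator does **not** model: instrument quality decay and
quality-correlated errors, fragmentation/coverage bias, paired-end layout,
RT drop-off at the crosslink, or any sequence preference of the reagent.
Benchmark percentages therefore speak to alignment-and-parsing accuracy
under the stated error model, not to wet-lab performance on real libraries.

`run_benchmark_ladder()` reproduces the four-stage optimization ladder —
stock aligner scoring, tuned scoring, plus ambiguity removal, plus edge
matching — on one simulated read set. Stages with ambiguity removal are
scored over the truth reads whose *encoded* junction is unambiguous (the
truth table flags these with the same slide test); without that denominator
the documented accuracy gain from ambiguity removal is arithmetically
impossible, since removing records can only shrink a fixed-denominator
percentage.

## Structure-aware evaluation

* `contact_distance()` — shortest path between two nucleotides in the graph
  with unit backbone edges (k, k+1) and base-pair edges (k, pair). A helix is
  traversed in about one step via its pair edges, which operationalizes
  "sequence distance with nested helices omitted".
* `spatial_distance()` — Euclidean distance between ribose 2'-hydroxyl
  oxygens, or between base-ring centroids (N1-C6 pyrimidine ring, plus
  N7-N9 for purines) for reagents that react with the base. Residues missing
  required atoms yield `NA` and are excluded (and tallied) downstream.
* `roc_auc()` — profile entries are labeled tertiary contacts when their 3D
  distance is below 15 Å *and* their contact distance exceeds 10; TPR/FPR are
  swept over distinct net-rate thresholds (tied rates enter together, making
  an all-tied profile score exactly 0.5) and AUC is the trapezoid sum, which
  equals the concordant-pair (Mann-Whitney) statistic.
* `shift_grid_auc()` — re-scores the classifier after shifting 5' sites 0-5
  nt downstream and/or 3' sites 0-5 nt upstream; the argmax reads off the RT
  landing offset. A profile whose 5' sites are offset by −2 recovers its AUC
  maximum at (2, 0).

## Numerical and design choices

* Coordinates are 1-based closed intervals everywhere; SAM POS is adopted
  unchanged; RNA `U` is normalized to `T` at ingest (reads are cDNA).
* The deletion-table dialect (column order, `#` metadata header recording
  version and parameters, full-precision rates, net-rate-descending order
  with deterministic tie-breaks) is fixed by this package.
* PDB residues are aligned to reference positions by an explicit user-supplied
  offset; silent heuristic mapping is rejected because a misalignment corrupts
  every downstream distance.
* Depth counts the full footprint of a read, deleted positions included: a
  read spanning a deletion still evidences sequencing through that locus.
  "Downstream of the 3' site" is inclusive of the site itself
  (positions `three .. three+4`).
* Edge matching examines the 5' flank first, then the 3' flank, alternating
  until both are exact; alternation avoids one-sided drift. Dedupe keys are
  `(read_id, five, three)` after correction.
* Zero net rates are removed after background subtraction (the subtraction is
  a denoising step); site shifting drops junctions whose shifted sites cross.
* Top-fraction selection takes `ceiling(fraction × N)` entries, ties broken
  by ascending site pair for determinism.

## Problem sizes and known limitations

The bundled checks run the ladders at 20,000 reads in the test suite and
100,000 reads in `scripts/acceptance.R`; the scored quantities are
percentages and are scale-free (their standard error at 20,000 reads is
already below half a point).

Known limitations, measured on the bundled benchmark:

* BWA-MEM silently drops the shorter chain of a split read when it is less
  than about half the primary chain's length. Such reads surface as a single
  soft-clipped alignment with no supplementary record, and their deletion is
  unrecoverable without realigning the clipped sequence — which this package
  deliberately does not do. On noise-free data this affects roughly 0.3% of
  reads; they are counted as undetected.
* An RT mismatch that happens to fall inside a junction's 3-nt flank makes
  edge matching shift a correctly placed junction outward (or drop it after
  10 moves). On the deletion benchmark this costs the edge-matching stage
  about one percentage point of exact matches relative to the
  ambiguity-removal stage.
* Benchmark accuracies on the deletion-insertion set depend visibly on the
  junction-insertion length distribution, which is configurable because the
  original empirical distribution is not available in tabulated form.
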