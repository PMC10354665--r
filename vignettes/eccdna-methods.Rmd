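---
title: "Methods: split-read eccDNA calling, junction correction, and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-read eccDNA calling, junction correction, and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and design choices behind
`eccprofiler`, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open choices were resolved.

## The calling model

A small eccDNA leaves two complementary traces in a paired-end alignment of
a circle-enriched library:

* one read of a pair maps **uniquely and contiguously** inside the circle
  body (operationalized here as a single-match-block CIGAR with soft/hard
  clips under 5 bp and mapping quality at least 20 — the threshold is
  configurable, since "uniquely mapped" has no universal quantification);
* the other read is a **split read**: its first segment (in template
  orientation) maps up against the circle *end* and its second segment maps
  from the circle *start*, i.e. the second segment's locus lies upstream of
  the first's on the same chromosome and strand. The start of the second
  mapping is the circle start; the end of the first mapping is the circle
  end.

Evidence rows are grouped by the exact (chrom, start, end) triple after
junction correction; a group becomes a call when it has at least
`min_support` distinct supporting reads (default 1 — every junction is
reported, and stringency is the caller's knob, not a hidden filter). Two
support counts are exposed: `n_evidence_reads` counts every evidence row
including duplicate-flagged reads (duplicates are retained by default so no
junction is missed), while `n_split_support` counts distinct read
identifiers, the quantity used for abundance work. Inverted junctions
(segments on opposite strands) are returned in a side channel rather than
called: simple circles have co-oriented junction segments, and inversion
artifacts would otherwise masquerade as circles. The mate-anchor check asks
for *any overlap* of the mate with the circle interval, not containment,
because rolling-circle templates let a mate straddle the junction.

Coordinates are 0-based half-open everywhere inside the package (BED
convention); human-readable report names (`format_call_names()`) print
1-based inclusive coordinates.

## Direct-repeat junction correction

If the `k` bases at the circle start equal the `k` bases immediately
following the circle end (a flanking direct repeat), the aligner can place
the split boundary at any of `k + 1` offsets; different reads of the same
circle then disagree by up to `k` bp. The correction computes, per evidence
row, the maximal window of equivalent offsets by extending exact sequence
matches leftwards (common suffix of the sequences ending at the two
breakpoints) and rightwards (common prefix of the sequences starting
there), then shifts both breakpoints left by the full leftward extension.

Choices made here:

* **Canonical offset = leftmost.** No convention is canonical a priori;
  leftmost matches common aligner normalization and makes the correction
  idempotent.
* **Exact matches only**, consistent with the equivalence being exact
  sequence identity; a mismatch-tolerant extension would blur the window.
* The search is capped at 50 bp (`max_shift`) and truncated at chromosome
  edges; `repeat_shift_window` records the number of equivalent offsets
  beyond the canonical one, which equals the flanking repeat length.

`find_direct_repeat()` re-scans canonical coordinates independently (longest
common prefix of the start-anchored and end-anchored sequences, capped at
20 bp — the repeats of interest are short, and 20 bp is beyond anything the
size strata resolve). The repeat fractions reported by
`repeat_fraction_by_size()` use this independent re-scan rather than the
correction windows, so the two computations cross-check each other.

## Confident regions and multi-fragment assembly

Cross-chromosomal junction evidence defines candidate region boundaries: a
breakpoint `b_start` joined *from* another chromosome opens a region, a
breakpoint `a_end` joined *to* another chromosome closes one. Each opening
breakpoint is paired with the nearest downstream closing breakpoint;
candidates longer than 100 kb are rejected (desk-scale circles are orders of
magnitude smaller; the cap guards against spurious pairings). A region is
emitted only if every base is covered by at least one read, with one
deliberate nuance: the first `w` bases of a region, where `w` is the
direct-repeat window at its opening junction, are sequence-identical to the
junction partner's downstream flank, so the aligner may place reads on
either copy; the coverage requirement therefore starts after the window.
Coverage counts all non-secondary alignments (whether only region-assigned
reads should count is genuinely ambiguous; counting all reads is the
conservative direction for *detecting* gaps only when they are real).

Assembly builds a directed graph (regions as nodes, junctions as edges
weighted by split-read support) and reports simple cycles of length 2 and 3
with pairwise distinct chromosomes, each rotated so the lexicographically
smallest fragment comes first. Longer cycles are left as unassembled
regions: two- and three-fragment circles are the structures with empirical
support, and merging longer cycles would manufacture structures the
evidence cannot distinguish from overlapping shorter ones. Regions shared
between cycles are all reported and flagged rather than greedily assigned.

## The synthetic data generator

The generator is the package's study stand-in, and its defaults are the
study conditions, not tuning knobs:

* **Sizes**: Gaussian mixture with modes 201 and 348 bp (sd 15/20, equal
  weights) — the nucleosome-ladder bimodality of small eccDNA.
* **Reads**: 150-bp paired-end; library fragments Normal(250, 25) bp,
  matching 200–300 bp circle-sequencing fragment sizes.
* **Chemistries**: `rca` builds a tandem concatemer of the circle with a
  geometric copy number of mean 5 (no amplification depth is published for
  rolling-circle protocols; the value is configurable and only the
  *existence* of multiple copies matters for read-level properties);
  `tagmentation` uses a two-copy template so fragments can wrap the
  junction once without amplification.
* **Direct repeats**: each circle plants a repeat drawn uniformly from
  0–10 bp (configurable up to 20) at every junction, and the simulator
  emits each split read's boundary uniformly among the legal offsets —
  exactly the artifact the correction must undo. The flanking homology is
  pinned to exactly the planted length by forcing mismatches just outside
  the window, which makes truth coordinates the canonical leftmost
  representation (otherwise chance homology would shift the canonical
  junction off the planted coordinates for ~1 in 4 circles, and
  "exact-breakpoint" comparisons would be ill-defined).
* **Depth** is calibrated analytically: the number of library fragments per
  circle is chosen so the expected number of junction-spanning split reads
  per junction equals `depth`, accounting for the 20-bp minimum split
  segment (shorter segments are soft-clipped without a supplementary, as a
  practical aligner would) and the finite concatemer.
* Reads are emitted as already-aligned SAM records in forward-genome
  orientation with bwa-mem-style primary + supplementary pairs linked by SA
  descriptors, MAPQ 60, and an optional duplicate-flag fraction; an
  optional FASTQ export supports integration tests against a real aligner.
  Sequencing errors default to 0 because the pipeline operates
  post-alignment and error modelling is orthogonal to every property under
  test.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: base-quality and indel errors, GC and
mappability bias, repetitive-genome multi-mapping (the toy genome is
uniform random, so MAPQ is honestly 60), chimeric artifacts of rolling
circle amplification, mitochondrial circles, and strand-asymmetric
fragments (all truth fragments are placed on the plus strand; the caller's
orientation logic is exercised by reverse-strand *reads*, which the
simulator does emit).

## Annotation, binning and enrichment

Derived tracks follow the usual conventions: promoters are 2 kb upstream of
genes (strand-aware; upstream of a minus-strand gene extends rightwards),
immediate downstream regions 2 kb downstream, CpG flanks 2 kb on each side
of islands, and distal intergenic is the genome minus all genic/CpG/derived
classes. Junction classification is **multi-label**: both breakpoints of a
call are counted as loci (configurable to start-only), and a locus receives
every class containing it, because the per-class double normalization
treats classes independently — a priority hierarchy would silently couple
them.

The per-class score `(junction_count / total_junctions) / (class_bp /
genome_bp)` equals 1 in expectation under uniform placement; class
coverages use merged (deduplicated) intervals, and zero-coverage classes
are excluded with a warning rather than producing infinities.

Genome distributions are compared on non-overlapping 1-Mb bins (trailing
partial bins kept; each call assigned by its start breakpoint). The
two-sample Kolmogorov–Smirnov comparison treats each distribution as an
empirical sample over the ordered bins — every call contributes its bin
index — so identical distributions give D = 0 and point masses in distinct
bins give D = 1. Applying a KS test to binned genome positions is itself a
convention (the underlying 2-D layout has no unique 1-D embedding); the
bin-index convention is recorded here because other embeddings would change
D.

The enhancer test scores each sample's unique multi-chromosomal joined
regions as `(fraction of regions hitting ≥ 1 enhancer) / (merged enhancer
bp / genome bp)` — a region counts once however many enhancers it touches —
and compares against length-matched random regions (chromosome chosen
proportional to length, start uniform; seed-reproducible). The null summary
per sample is the mean over `n_draws = 20` draws (a single-draw mode exists
for protocol fidelity); observed and null are paired per sample in an exact
one-tailed Wilcoxon signed-rank test. With five samples the smallest
attainable one-tailed p is 1/32 ≈ 0.031, which the result object reports
alongside the p-value so small-sample significance is never over-read.

## Exact tests

Signed-rank and rank-sum p-values are exact for n ≤ 25, computed with the
distribution-counting (shift) recurrence over doubled mid-ranks — doubling
keeps tied mid-ranks integral, and the recurrence enumerates the 2^n sign
assignments (or C(n, k) group assignments) on the observed tie structure
without materializing them. Beyond n = 25 a normal approximation with tie
correction and ±0.5 continuity correction takes over; the cutoff is far
above the 3–8 samples typical of this assay, so every p-value that matters
here is exact. Degenerate inputs (all-zero differences, identical constant
groups) return p = 1 with a flag instead of erroring. The two-sample KS
test wraps `stats::ks.test` (asymptotic p; ties make it approximate, as
usual).

## Abundance, recurrence, biomarkers

Gene abundance accrues each call's `n_split_support` to every gene whose
body it overlaps (a call spanning k genes counts for all k; an optional
±2 kb extension exists because "associated gene" has no canonical overlap
rule). Normalization is counts per million total split reads per sample;
raw integer counts are what the export writes, since downstream
negative-binomial tools do their own normalization. Deduplicated support is
used by default (duplicate inflation would bias abundance), configurable.
Recurrence uses exact (chrom, start, end) identity by default — after
base-pair junction correction, identical circles really are identical — with
optional single-linkage tolerance clustering for cross-pipeline input;
clusters wider than twice the tolerance are flagged. Breakpoint-flank
export writes 150-bp records per breakpoint (50 bp inside the circle +
100 bp outside; the inside/outside orientation of the 50-bp component is a
documented choice, as the opposite reading is also defensible), dropping
and counting records that would cross a chromosome edge.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale, chosen so each
property is measured with adequate statistics: 500 single-fragment circles
at depth 30 for caller recovery, 50 two- + 20 three-fragment circles for
assembly, n = 2000 for size-peak localization, 5000 uniform loci × 50–100
seeds for enrichment calibration, and 20 five-sample replicates for the
enhancer-null size check. Every random stage derives an independent child
seed from one master seed (a fixed integer hash of stage labels), which is
what makes full pipeline reruns byte-identical. Peak detection smooths the
1-bp size histogram with a 5-bp moving average and suppresses local maxima
within 50 bp of a higher one (`pracma::findpeaks`), since nucleosome-ladder
modes are ≥ 100 bp apart and shoulder maxima otherwise dominate the
ranking. Ties in peak height break toward the smaller size; cumulative size
boundaries use the "fraction strictly shorter than x" convention.

## Known limitations

* The caller assumes co-oriented junction segments; inversion circles are
  surfaced but not reconstructed.
* Reads wrapping a sub-read-length circle more than once keep only their
  first wrap (primary + one supplementary), losing later wraps.
* Confident-region pairing takes the nearest downstream closing breakpoint;
  nested or overlapping multi-fragment structures on one chromosome are not
  resolved.
* The enrichment score is a ratio estimator; for classes covering ≪ 1% of
  a small genome its variance is large, which is why calibration checks are
  restricted to classes covering ≥ 5%.
* On real libraries, duplicate marking, mappability and reference quality
  dominate error modes that the synthetic data cannot exhibit.
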