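---
title: "Detecting transgene integration islands from noisy long reads"
author: "islandseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transgene integration islands from noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandseq)
```

## The problem

When exogenous DNA is delivered into a nuclear genome by biolistic
bombardment, it rarely integrates as a single clean copy. Instead it forms
*integration islands*: long contiguous insertions assembled from many
fragments of the delivered plasmid, concatenated in mixed sense and
antisense orientations, at one or two loci per transformant. Such islands
can reach hundreds of kilobases — far longer than any single sequencing
read — so characterising them requires noisy long reads (nanopore-class:
5–10× coverage, read lengths from hundreds of bases to ~190 kbp, ~15%
error) and an analysis that is careful about what can and cannot be
concluded from partial evidence. Conversely, DNA delivered by bacterial
conjugation is maintained as a free circular episome, and the analysis
must be able to demonstrate a *negative*: that no episome fragment
integrated anywhere.

`islandseq` implements this analysis as a reusable pipeline: alignment of
reads to the delivered construct and to the host reference, a
false-positive filter for construct regions copied from the host genome,
per-read classification, island calling with site resolution and size
estimation, concatemer structure reconstruction, genomic feature
annotation, and the coverage arithmetic used to size islands that no read
pair of borders can bound. A synthetic-data generator reproduces the whole
data-generating process with machine-readable ground truth, so every stage
is testable without any external download.

## Read classification

Every read receives exactly one class:

* **genome_only** — aligns to the host reference and carries no unmasked
  construct signal;
* **construct_only** — unmasked construct alignment but no genomic flank of
  at least `minFlank` bp. These reads come either from free episomes or
  from deep inside an integration island; the two are indistinguishable by
  construction, and the pipeline does not attempt to separate them;
* **left_border / right_border** — one genomic flank abuts a construct
  block. Sides are named on the *genome* axis (the left border is the flank
  reaching the smaller genomic coordinate), after normalising
  reverse-complemented reads;
* **spanning** — genomic flanks on both sides anchored to one locus: the
  read traverses the entire island;
* **false_positive** — construct alignment exists but survives the
  shared-native mask with less than `minConstructExtent` bp (see below);
* **ambiguous** — flanks anchor to different chromosomes or to loci more
  than `clusterDistance` apart (possible chimeric molecules); logged and
  excluded from island calling;
* **unmapped** — nothing aligned.

### The shared-native mask

Constructs routinely carry promoter and terminator segments copied verbatim
from the host genome. A purely genomic read overlapping such a locus
produces a genuine construct alignment and would be counted as construct
evidence. The filter aligns the construct sequence against the reference,
takes the union of the construct-side intervals of all passing hits, pads
each by `maskPadding` (default 10 bp) and merges. A read's *unmasked
construct extent* is the per-base union of its construct-aligned target
intervals minus the mask; reads below `minConstructExtent` (default 100 bp)
are false positives. Masked construct alignment still marks
construct-compatible sequence, so the *construct block* used to delimit
genomic flanks spans all construct hits — otherwise the genomic alignment
of a shared segment inside an island read would masquerade as a flank.

## Island calling

Border and spanning reads carry genomic junction estimates: for a flank
anchored genome-left of the island, the maximum genomic coordinate the
flank alignment reaches; for a genome-right flank, the minimum. Anchors on
one chromosome within `clusterDistance` (default 10 kbp, single linkage)
form one island candidate. The insertion site is the gap between the
left-flank maximum and the right-flank minimum, reported 1-based inclusive;
its width is the *resolution*. When the flanks overlap — junction
microhomology makes the precise insertion point intrinsically ambiguous —
the site collapses to a zero-width point at the midpoint.

Island size is exact when a spanning read exists (the read-space distance
between its two junctions, which is robust to deletions inside the island
alignment), otherwise a lower bound: the largest left-border construct
extent plus the largest right-border construct extent. The bound is sound
in the regime the method targets (islands much longer than reads); for an
island comparable to read length, both border reads can reach past its
midpoint and the sum can exceed the truth — but such islands are
essentially always spanned, and the exact path is used instead.

## Concatemer structure

The construct-aligned portion of a read is segmented into ordered,
oriented fragments by chaining construct hits along the read (overlaps are
resolved by keeping the longer hit, ties by identity then position).
Fragment boundaries are identifiable only up to the microhomology at the
joints between fragments: when two fragments happen to share a few bases
at their junction, any maximal-alignment decomposition may shift the
boundary by those few bases. Tests therefore compare structures at a
15 bp tolerance while requiring exact fragment counts and orientations.

## Coverage arithmetic

Fold coverage is total nucleotides over genome size; the genome size is an
explicit parameter because the effective denominator of a real run
(organelles, unplaced scaffolds) rarely equals the nuclear assembly
length. The probability that every base of the genome was seen at c-fold
random coverage is the Clarke–Carbon expression `1 − exp(−c)`; at the
lowest coverage in the study regime (5.8×) it already exceeds 99.7%.

Islands that no spanning read bounds can still be sized in aggregate by a
read-budget argument: construct-only reads are drawn from integrated
construct material, so their nucleotide total `ni` divided by the per-base
sequencing depth estimates the total integrated length, and subtracting
the islands already sized leaves the unresolved remainder:

`L_unresolved = ni / c − Σ l_known`

Two implementation choices matter here. First, `ni` counts the full read
lengths of construct-only reads (a flag switches to construct-aligned bases
only). Second, the depth `c` used in this formula is the *host-genome*
coverage, `(total_nt − ni) / genome_size`: the construct-only nucleotides
are the very budget being converted into length, so leaving them in the
depth estimate would count the islands twice. At whole-genome scale the
correction is negligible (`ni` is a fraction of a percent of the run); at
the reduced scale of the test suite, where islands are a few percent of
the genome, it is not.

The estimator inherits an edge deficit: reads that straddle an island
boundary are border reads, not construct-only reads, so `ni`
under-represents the island ends by roughly one length-biased mean read
length per side. With the study's read-length regime (log-normal, mean
~7 kbp, heavy tail) this contributes a downward bias of order 5–10% for a
250 kbp island, which is why the calibration criterion is stated at the
20% level and why the estimate improves as islands grow relative to
reads, not as coverage grows.

## The synthetic data generator

The generator emulates the study conditions end to end:

* **Host genome** — i.i.d. random chromosomes at 48% GC. Default desk
  scale: 2 chromosomes, 1.2 + 0.8 Mbp, preserving the island ≫ read-length
  geometry of the real 27 Mbp genome at roughly 1/15 scale.
* **Construct** — 6.5 kbp circular plasmid (3.5 kbp novel backbone, 2 kbp
  novel coding sequence, two 500 bp segments copied verbatim from the host:
  a promoter and a terminator). The episome analogue is 10.8 kbp. The
  copied intervals are recorded as shared-native truth.
* **Islands** — concatemers of construct fragments, drawn uniform
  500 bp–6.5 kbp in length with antisense probability 0.5 (the study
  reports mixed orientations but no fragment statistics; these defaults
  are stated, not inferred). Default lengths 10–50 kbp at two loci.
  Fragments whose construct coordinates would continue a nearby
  same-orientation fragment's alignment diagonal within 300 bp are
  redrawn: such joints are invisible to any chaining aligner, so
  excluding them makes the planted structure the unique recoverable
  decomposition.
* **Junctions** — clean by default; optionally up to ±`junctionIndelMax`
  bp of host deletion and random insertion at each border, emulating
  junctions that cannot be resolved to the base.
* **Reads** — log-normal lengths (mean 7 kbp, sigma 0.9, matching the
  6.8–16 kbp per-run means of the study regime, with a tail reaching
  ~190 kbp), truncated at the molecule length; circular molecules are read
  from a doubled sequence and never beyond one circumference. Errors are
  independent per-base substitutions/insertions/deletions at 5% each (the
  study states only the 15% aggregate). Total emitted nucleotides are
  trimmed to the requested coverage exactly.
* **Truth** — per-read source intervals and classes, per-island insertion
  points, lengths and structures.

What the generator does *not* emulate — genomic repeats, base-quality
structure, chimeric/adapter artefacts, error bursts, non-uniform coverage
— bounds what passing tests show: they validate the logic of
classification, clustering, sizing and estimation under the stated noise
model, not robustness to every artefact of real flow cells.

### Junction microhomology and truth containment

When the island sequence happens to begin or end with the same bases as
the genomic sequence flanking its insertion point, any insertion point
within that homology tract produces the *identical* transgenic sequence.
The benchmark therefore scores a called site as containing the truth when
it contains any point of the equivalence interval, which is computed from
the wild-type and transgenic sequences; demanding the planted coordinate
itself would declare failures that no method could avoid.

## Numerical and design choices

* Internal mapper: exact 13-mer seeding, diagonal-band grouping (60 bp
  band), chaining along the read with a 1 kbp within-chain gap. At 15%
  error the gaps between error-free 13-mers form runs that regularly
  exceed 200 bp, so the chain gap must be much larger than the hit-merge
  gap; 1 kbp stays below any structural distance the pipeline needs to
  distinguish. Chains of fewer than five seeds are discarded — a genuine
  hit of even the minimum length carries a dozen or more exact 13-mers at
  15% error, while a chance diagonal coincidence of a few seeds can slip
  past the identity threshold. Sparse terminal seeds (more than 250 bp
  from the rest of a chain) are trimmed: a lone errored k-mer matching
  in-band past a
  junction would otherwise drag a flank boundary hundreds of bases into
  the island, while the cost of trimming a genuine terminal seed is only
  a conservative, slightly shorter flank.
* Hit identity is estimated from chained seed density as
  `(m / windows)^(1/k)` — exactly 1 for error-free hits, and a consistent
  estimator of per-base accuracy under the independent-error model —
  rather than from base-level alignment; boundaries from terminal seeds
  are exact on clean data and biased *inward* under error, which is the
  safe direction for junction estimates. An exhaustive dynamic-programming
  local aligner serves as the independent oracle in the tests.
* Default thresholds: hits ≥ 100 bp at identity ≥ 0.70 (merge gap
  200 bp); classification at 100 bp minimum unmasked extent, 200 bp
  minimum flank, 10 kbp cluster distance, 10 bp mask padding. The source
  analysis does not state its thresholds; these are chosen to admit the
  15% error regime while excluding random 13-mer chains, and all are
  exposed in the configuration.
* Report coordinates are 1-based inclusive; all interchange files are
  0-based half-open BED convention; the internal frame is 0-based
  half-open throughout.
* Upstream/downstream in feature context are genome-coordinate-based (not
  transcript-strand-based) and distances are boundary-to-boundary gaps,
  0 when touching, reported within 1 kbp.
* One-sided candidates (anchors on a single side) are reported and
  flagged, never silently dropped.
* Fold-change bins are lower-inclusive half-open
  (`[0,10) [10,250) [250,800) [800,1500) [1500,∞)`); a fold change of
  exactly 1500 lands in the top bin. Fold changes are ratios of
  arithmetic means on the linear scale.

## Problem sizes used by the test suite

The synthetic acceptance surface runs, per seed: integration lines at
2 Mbp / two islands of 10–50 kbp / 8× / 15% error (10 seeds, plus
error-free and ±20 bp junction-indel variants); episome lines at 2 Mbp /
6× (20 seeds); and size-estimator calibration on a 1.2 Mbp genome with a
10 kbp known and a 250 kbp unresolved island — the published island
geometry — at 4×, 8× and 16×. These sizes preserve the geometry that
drives the method (islands ≫ reads ≫ junctions) while keeping the full
suite comfortably within a desk-scale run.

## A worked desk-scale example

```{r example, eval = FALSE}
line <- simulateIntegrationLine(seed = 1)
res <- detectIntegration(line$reads, line$wildtype, line$construct)
res$summary
res$islands[, c("chromosome", "site_start", "site_end", "resolution",
                "complete", "size_bp")]
runBenchmark(res, line$islands, line$truth,
             wildtype = line$wildtype, transgenic = line$genome)
```

## Known limitations

* Construct-only reads internal to a large island cannot be assembled into
  the island's full sequence; their repetitive concatemer content defeats
  overlap layout, which is exactly why the read-budget estimator exists.
* The incomplete-island lower bound is not sound for islands shorter than
  the read-length scale (see above).
* The mapper targets the regime it was built for: kilobase-scale noisy
  reads against a reference and a small construct. It produces interval
  hits, not base-level alignments (no CIGAR), and SAM ingestion is out of
  scope; precomputed PAF/BLAST tabular alignments can be supplied instead.
* Expression screening implements the binning and dispersion arithmetic
  only; flow-cytometry file parsing, gating and inter-library hypothesis
  testing are out of scope.
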