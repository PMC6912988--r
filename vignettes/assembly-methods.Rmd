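---
title: "Reference-guided transcript assembly: models, parameters and design choices"
author: "spliceflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided transcript assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceflow)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It covers the assembly model, the long-read
mode, the super-read and evaluation modules, the synthetic-data generator
and its scope, and the numerical choices that matter.

## The assembly model

The input is a set of spliced alignments: each read contributes an ordered
chain of exon blocks (0-based, half-open internally; SAM's 1-based
coordinates are converted on input, which removes off-by-one ambiguity from
junction keys). Reads aligned to the identical location are collapsed into
one record with a count; mate pairings survive collapsing as links between
collapsed locations, because reads collapsed together need not have their
mates at the same place.

**Noise filters.** Junctions accumulate weighted support (1/NH per
alignment) and per-side anchors — the aligned bases flanking the junction
inside a supporting read. A spliced read is dropped when

* any of its junctions falls below `min_junction_support` (default 1 read),
  or below 1.25× that threshold if the read's mismatch rate (NM / aligned
  length) exceeds 1% — error-prone spliced alignments must clear 25% more
  support;
* any junction lacks a 10 bp anchor on each side in at least one supporting
  read, raised to 25 bp on both sides for introns longer than 100 kb.

The mismatch filter is applied per read to all of its junctions (a read with
several junctions is either globally trustworthy or not); when NM is absent
the rate is 0 and the filter is inactive, since errors cannot be fabricated.
Multi-mapped reads contribute fractional weight 1/NH throughout — the
standard convention.

**Splice graph.** Within a bundle (alignments separated by at most
`max_gap` = 50 bp; 200 suits gap-rich genomes), node boundaries are the
union of junction donor/acceptor sites, coverage start/end transitions, and
guide-annotation exon boundaries. Each covered maximal segment is a node
with mean per-bp coverage; junction edges join the nodes flanking each kept
junction, and adjacency edges join contiguous nodes only where at least one
read block spans the shared boundary — abutting coverage without a spanning
read is not evidence of connectivity. Guides add boundaries and edges with
zero read support: they constrain structure, never abundance. Bundles
containing both XS strands are split into two graphs; strand-unknown
(typically unspliced) alignments contribute coverage to both, mirroring
common practice.

**Bit-vector paths.** Reads, fragments and transcripts are sets of node and
edge bits. The dense layout assigns bits 0..n−1 to nodes; the edge formula
*n·i + j* as usually printed collides with the node bits (edge (0, j) maps
onto node bit j), so the edge region is offset by *n*; the sparse encoding —
bits only for nodes/edges that exist — is what the assembler actually uses,
which makes the dense layout immaterial in practice. A mate pair is an
*interrupted* path: bits for both mates, none for the unobserved inner gap.
Compatibility of a read with a transcript path requires bit containment plus
contiguous embedding of each read part in the transcript's node sequence —
a read that skips a node the transcript visits is incompatible.

## Isoform extraction and quantification

Transcripts are extracted iteratively. Each round seeds at the
maximal-coverage node and extends in both directions. A candidate edge is
scored by the total weight of *still-unassigned fragments that span it and
do not conflict with the partial path* (a fragment touching a node the path
skips, or an edge the path contradicts, is excluded). This
fragment-consistency guidance is what prevents the residual unique reads of
two different isoforms from being welded into one chimeric path after their
shared reads have been consumed. When no unassigned fragment spans any
candidate edge, the remaining, then the original, support ranking decides —
so a low-abundance isoform sharing terminal exons with an already-extracted
one is completed rather than truncated. Ties break toward the
higher-coverage neighbour, then the smaller node index; everything is
deterministic and no RNG is consumed.

Each accepted path is assigned the full remaining mass of its compatible
fragments (mass = weight × aligned bases), which are then removed from the
pools; total mass is conserved exactly at every round. The per-round
abundance gate is the minimum compatible support over the path's edges
(mean node coverage for single-node paths); a path with zero compatible
mass is rejected and its seed retired. Rounds stop when no node retains
`min_transcript_coverage` (default 1 read/bp) unassigned coverage, or after
`n_edges + 1` rounds.

Final coverages are re-estimated over the whole candidate set by EM:

* each fragment's mass is distributed across its compatible candidates in
  proportion to mass/effective-length — a per-base rate. Effective length is
  the transcript length minus the median fragment span, because fragment
  *starts* are drawn from `L − span + 1` positions: shorter isoforms have a
  higher start density, and ignoring this biases mass toward long isoforms;
* interrupted mate pairs carry fragment-length information the bit sets do
  not: the implied inner gap of the fragment on each candidate (residues of
  the flanking nodes plus the nodes in between) is compared with the
  fragment-length estimate from unambiguously assigned pairs, and candidates
  further than `frag_gap_tol` (default 60 bp) from it are dropped. Without
  this, a pair whose gap would have to swallow a whole cassette exon on the
  longest isoform still counts for it, and EM drifts;
* transcripts below `min_transcript_coverage`, or below
  `min_isoform_fraction` (default 0.01) of the locus maximum, are dropped.
  Both defaults are configurable conventions, not measured constants.

When end trimming is on (it is off in long-read mode, and `-t` disables it),
terminal exon bases whose per-bp coverage is below `trim_fraction` (0.1) of
the transcript's mean are walked back; a terminal exon never shrinks below
1 bp. The 0.1 constant is a package convention; only the existence of the
behaviour and its switch are standard.

### Accuracy expectations

On noiseless uniform-coverage fixtures the assembler recovers every
cassette isoform exactly and the EM coverages track truth with a mean
absolute relative error around 1%. Per-transcript error is depth-limited:
an isoform's distinctive evidence is a few dozen fragments at coverage
10–30, so individual estimates carry an irreducible sampling/aliasing
component of order 1/√n (up to ~10% at the low end). Aggregate accuracy is
therefore what the acceptance checks assert. A junction-count linear
deconvolution was evaluated as an alternative estimator and discarded:
junction-crossing windows are narrow, so its shot noise exceeds the EM's.

## Long-read mode

Long reads carry 5–15% alignment error, with the damage concentrated
around splice sites. Two mechanisms address this:

* **Splice-site correction.** Sites are tabulated with total and low-error
  support (low-error: mismatch rate ≤ `high_error_threshold`, default 0.02 —
  the "high-error" trigger has no standard constant, so this is a
  configurable package default; guides contribute weight-1 low-error
  support). For each site of each high-error read with zero low-error
  support, the site moves to the most-supported low-error site within
  `correction_window` = 10 bp (ties: nearest, then smaller coordinate). A
  move that would create an empty exon or non-positive intron is skipped and
  logged. Correction is idempotent: a corrected site has low-error support,
  so the trigger cannot fire twice.
* **Graph pruning.** Spurious exons from random indels can blow the graph
  up. Edges are removed from least to most read-supported until fewer than
  `max_nodes` = 1000 remain; a node is dropped only when it loses every
  incident edge *and* has no unspliced read coverage, so single-exon
  transcripts survive; guide edges are never removed. Reads spanning pruned
  nodes are re-encoded as interrupted paths, exactly like mate pairs; a read
  whose bits are all pruned leaves the assembly. Removal order is
  support-sorted up front, so the event log's supports are non-decreasing by
  construction.

## Super-reads

Short reads are extended into synthetic long, low-error reads. A canonical
*k*-mer table (a *k*-mer and its reverse complement share an entry; k
defaults to 25, a package convention) is built with *no* minimum-count
filter — transcripts can legitimately be covered by a single read, unlike
genomes. *k*-unitigs are maximal chains in which every internal *k*-mer has
a unique predecessor and successor; each read whose terminal *k*-mers place
uniquely in unitigs is extended to the unitig ends. Reads map to aligned
super-reads iff they (or their reverse complement) are exact substrings;
coverage is distributed by the same EM (unique-first initialisation,
proportional redistribution, equal split for all-zero denominators), and
super-read alignments are emitted as SAM with an `XC:f:` coverage tag. The
assembler weights such records by the tag and ignores their first/last k−1
aligned bases, which may extend into alternatively spliced exons.

Note one degenerate regime visible at toy scale: with k = 3, sequences
whose adjacent k-mers are reverse complements of each other (homopolymer
runs, `ACGT`-type palindromic steps) legitimately break unitig chains under
canonical counting. Test fixtures avoid such sequences; at k = 25 on real
data the effect is negligible.

**EM stopping.** Tolerance 1e-6 (relative to total mass) on the maximum
per-item change, with a 1000-iteration guard. Mass conservation holds at
machine precision at every iteration by construction. A component
collapsing toward zero mass decays sub-geometrically, so occasionally a
random assignment matrix is still drifting (just above tolerance) at the
guard; this is a property of boundary-collapsing EM, not an accuracy
problem — the conserved masses of the surviving components are stable far
earlier.

## Evaluation

A predicted transcript matches a reference transcript iff intron chains are
identical coordinate-by-coordinate and each terminal end is within 100 bp;
single-exon transcripts match when both interval ends are within the slack
(our reading — whether the end slack applies to single-exon transcripts is
not standardised). A reference matched by several predictions yields one
TP; the surplus predictions are FP, matching gffcompare's redundancy
handling. Strand-unknown predictions may match either strand, since
single-exon assemblies often lack an XS strand; intron identity likewise
ignores strand. Relative change is `100·(x1 − x2)/x2` — a move from 20% to
30% sensitivity is a *relative* increase of 50%. The union-reference helper
builds the "true" set for real-data comparisons as the union of annotated
transcripts any tool recovered, deduplicated structurally.

## The synthetic-data generator

`fixture_spec()` fixes the study conditions; one seeded RNG stream drives
everything, so equal seeds give byte-identical files.

* **Loci.** Each locus is a random exon/intron backbone (exons 80–300 bp,
  introns 60–400 bp, GT/AG written at intron boundaries) carrying one
  alternative-splicing cassette region: a run of adjacent internal exons,
  with the full chain plus one variant isoform skipping each cassette exon.
  Under this classic pattern every isoform has a private junction, so the
  locus is resolvable from short paired fragments. This is a deliberate
  scope decision: loci with several alternative events farther apart than
  the fragment span are *provably* unresolvable from such data (two
  different transcript sets explain every observable fragment equally
  well), so they cannot serve as recovery benchmarks; real genes with
  distant co-occurring events are exactly where short-read assemblers lose
  sensitivity, and passing these fixtures says nothing about that regime.
* **Short reads.** 75 bp paired reads (insert 250 bp), tiling each
  transcript deterministically at its truth coverage (distinct integers in
  10–30 reads/bp per isoform, so abundances are separable), NM = 0, correct
  XS and proper-pair flags.
* **Long reads.** Per transcript, a clean fraction (`p_clean` = 0.4, at
  least one read) stays error-free; the rest carry NM ≈ 3% of aligned
  length and have each junction independently jittered by ≤ 6 bp with
  probability `p_jitter` = 0.5 — error is modelled at the alignment level
  (block jitter plus the NM tag), which exercises every long-read code path
  without implementing an aligner. Optional truncation produces partial
  fragments. A jitter log records ground truth for restoration scoring.

What passing these fixtures shows — and what it does not: exact recovery on
noiseless cassette loci demonstrates the graph, compatibility, extraction
and EM machinery end to end, but says nothing about alignment noise,
coverage non-uniformity (fragment GC/positional bias), overlapping genes,
or distant-event isoform structure. Those remain the caveats for real data.

## Problem sizes and reproducibility

The shipped checks run at desk scale, chosen so the whole suite finishes in
minutes on one core: 50 three-isoform loci (~37k read pairs) for short-read
recovery, 12 loci of 8 long reads per transcript for correction and
long-read assembly, a 2000-node random graph for pruning, 100 random
matrices for EM, and exhaustive/random small instances (graphs ≤ 8 nodes,
sequences ≤ 200 bp with k ≤ 7, transcript sets ≤ 100) for every
brute-force oracle comparison. `scripts/acceptance.R --seed N` reruns the
full set from scratch; all randomness flows from the seed.

## Known limitations

* Heuristic extraction: the greedy fragment-guided walk is deterministic
  and exact on the shipped conditions but is not a global flow optimum;
  pathological residual configurations can still in principle merge
  isoforms.
* No FPKM/TPM, no cross-sample merge mode, single-threaded by design.
* BAM/CRAM input is out of scope (SAM text only); use `samtools view`
  upstream.
* The splice-site corrector only relocates sites supported elsewhere in the
  bundle: a junction whose every read is high-error (no clean read, no
  guide) is left untouched.
* Coverage estimates are fragment-level maximum-likelihood under uniform
  sampling; they inherit EM's limitations for components near zero and the
  depth-limited per-transcript error discussed above.
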