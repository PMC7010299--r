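---
title: "Detecting back-spliced RNAs from repeat consensus alignments"
author: "retrocirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting back-spliced RNAs from repeat consensus alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrocirc)
```

## The problem

Centromeric retrotransposons such as the maize CRM families exist in
hundreds of near-identical, often fragmented copies. Reads from their
transcripts cannot be placed at a unique genomic locus, so the standard
circular-RNA callers — all of which anchor back-splice junctions to unique
genome positions — are blind to circles arising from these repeats. The
alternative is to collapse the family onto a single consensus sequence and
to read the splice structure off the geometry of local alignments: a read
whose two aligned segments appear in *downstream-then-upstream* order on
the consensus reveals a back-splice junction, the hallmark of a circular
RNA. That is the strategy this package implements, together with a
synthetic-data generator that makes every stage testable without any
external data.

The biological system the generator emulates is a CRM1-like element whose
"donor" region is three contiguous sub-regions of 85, 253 and 269 nt
(607 nt total). One back-splice site — the 3' end of the 269-nt sub-region
fused to the 5' start of the 85-nt sub-region — supports three circular
isoform classes: a 354-nt circle (85 + 269, the 253-nt interior spliced
out), a fully retained 607-nt circle, and short 277–296-nt variants that
keep only the first 8–27 nt of the 85-nt sub-region. Linear RNAs
(RNA-85, RNA-269 and the forward-spliced RNA-85+269) cover the same
region, and reads touching the long terminal repeats form their own
class.

## Pipeline

1. **Pair merging** (`merge_pairs`): paired-end reads are 3'-quality
   trimmed at Phred 30 and joined at their best 3' overlap
   (score = matches − 2·mismatches, ties to the longest overlap,
   mismatch fraction ≤ 0.1, default minimum overlap 15 nt); merged
   products shorter than 25 nt are discarded and unmerged pairs travel on
   as two independent fragments.
2. **Consensus alignment** (`align_fragment`): a seed-and-extend local
   search over an 11-mer index, extended by an affine-gap Smith–Waterman
   kernel (match +1, mismatch −2, gap of length L costs 5 + 2L), on both
   strands. A hit is kept when its Karlin–Altschul e-value is at most
   1e-5 (lambda solved from the scores at uniform base composition,
   K = 0.62, database length = total consensus length) and its identity
   (matches over alignment columns) is at least 0.85. Accepted hits mask
   their read interval and the flanks are searched recursively, so a
   chimeric fragment yields non-overlapping segments.
3. **Anchor trimming**: a local alignment happily extends through flanking
   sequence that matches 60–80% by chance, which corrupts junction
   breakpoints. Every alignment is therefore trimmed back so it starts
   and ends with six consecutive matches. The exhaustive-scan oracle in
   the test suite applies the same rule, so the seeded search remains
   exactly comparable to full Smith–Waterman.
4. **Anchor rescue** (`rescue_anchors`): an 11-nt back-splice arm can
   never pass the e-value threshold on its own (its score is far below
   the significance point of ~19), yet such arms carry the junction
   evidence. Maximal unexplained read intervals of at least the word size
   are therefore matched ungapped against the consensus, with candidate
   placements proposed by exact 11-mer seeds, judged on their
   anchor-trimmed range (4-match anchors suffice here, because a rescue
   cannot over-extend beyond its interval), and ranked by fewest
   mismatches, then longest match — an exact short placement must beat a
   longer shifted one that absorbs foreign bases at the cost of a
   mismatch.
5. **Chaining and taxonomy** (`chain_segments`, `classify_fragment`):
   read-adjacent hits (gap and overlap each ≤ 10 nt) on one consensus and
   strand form chains; the best-scoring chain is the fragment's primary.
   Categories form a partition: LTR (any segment overlapping an LTR by
   ≥ 20 nt, taking precedence so the taxonomy stays exhaustive),
   NONSPLICED (one segment), NORMAL_SPLICED (collinear segments skipping
   an interior gap), BACK_SPLICED (exactly one downstream-then-upstream
   adjacency; other adjacencies must be collinear), AMBIGUOUS
   (anything else), UNALIGNED. Minus-strand chains are evaluated on the
   reverse-complement frame, making classification strand-invariant.
6. **Breakpoint refinement**: the two arms of a back-splice anchor
   ungapped mappings of the spanning read interval (left-anchored from
   the donor arm, right-anchored from the acceptor arm); the split
   maximizing total matches places the breakpoint, and a run of
   right-arm mismatches just after the split is treated as a candidate
   retained insert — the partially retained 8–27-nt piece of the short
   isoforms — which relocates the acceptor when it has a unique best
   placement (at most one substitution, with a one-mismatch margin over
   the runner-up) upstream in the consensus. The insert interpretation
   must beat the plain split by at least two matches, because a spurious
   placement adjacent to a sequencing error can gain at most one.
7. **Canonicalization and clustering** (`canonicalize_junction`,
   `cluster_junctions`): microhomology between the junction flanks makes
   the exact breakpoint ambiguous; all equivalent placements are shifted
   to the leftmost one, which makes cluster keys unique. Clusters carry
   the support-weighted modal coordinates and member read ids.
8. **Isoform reconstruction and verification** (`reconstruct_isoforms`,
   `divergent_pcr`, `genomic_origin_test`): retention patterns (skipped
   intervals between acceptor and donor) turn a junction into concrete
   circles in canonical acceptor-first rotation; in-silico divergent PCR
   demonstrates circularity (product on the circle, none on the linear
   form); and the genomic-origin test maps DNA reads to the assumed
   fused junction sequence (177 + 177 nt by default, mirroring the
   assumed 354-bp DNA) and counts reads covering the fusion point with at
   least 10 matched nt on each side — tolerating one residual read, as a
   chromatin-derived RNA remnant can produce a single apparent hit.
9. **Quantification** (`tabulate_classes`, `rpm_track`,
   `relative_enrichment`, `coverage_estimate`, `normalize_3c`):
   family-by-category count tables, reads-per-million tracks over
   MAPQ-filtered placements (≥ 20), RIP/input enrichment as a
   pseudocount-adjusted ratio of library proportions, base-level fold
   coverage, and the 3C-qPCR double normalization
   (target/reference in the sample over target/reference in the
   digested-and-ligated control template, efficiency E in (1, 2]).

## What the generator emulates, and what a green test establishes

`build_consensus` draws an i.i.d. A/C/G/T element with two identical LTRs
(default 450 nt each), gag/pol coding regions, the 85/253/269 donor
architecture and an intergenic spacer (4,707 nt in total at the defaults —
a reduced-scale element that keeps desk runs fast while preserving every
structural feature the pipeline relies on). `plant_elements` embeds full
and fragmented copies, on either strand, at 2% substitution divergence
(the study is silent on inter-copy divergence; 2% is a guess typical of
young LTR families and is exposed as a parameter).
`make_transcripts`/`simulate_reads` produce the isoform pool with
uniform, wrap-around fragment placement on circles, 125-nt paired-end
reads (the RIP-seq read length), a normal insert-size distribution
(default 180 ± 20 nt, clamped to the template), constant Phred-37
qualities, and uniform substitution errors. Circular abundances default
to five-fold below linear ones: the real ratio is orders of magnitude
smaller, but a desk-scale generator must produce enough junction reads to
measure recovery. Indels, quality-dependent errors, PCR duplicates and
composition bias are *not* modeled, so a green suite establishes
correctness of the geometry and bookkeeping, not robustness to every
real-world artifact.

A junction-crossing read is counted as *identifiable* when each arm
provides at least the seed word (11 nt) of anchorable sequence beyond the
junction's microhomology run — bases inside the run are legitimately
claimed by either arm, so they cannot count as evidence — and, for the
short isoforms whose retained piece is below the word size, when the
acceptor side reaches the word length beyond the retained piece. The
acceptance suite demands exact recovery of the canonical junction for
100% of identifiable crossing reads at zero error rate and at least 95%
at a 1% substitution rate.

## Numerical and design choices

- **Coordinates** are 1-based inclusive everywhere, matching R and
  Bioconductor convention; files on disk (TSV, GFF3) are likewise 1-based
  inclusive, except BedGraph, which is 0-based half-open as the format
  requires.
- **Affine gaps** cost open + L·extend (5 + 2L), the same convention as
  `Biostrings::pairwiseAlignment`, which keeps the oracle comparison
  exact to the integer.
- **Karlin–Altschul K** is 0.62, the tabulated ungapped BLASTN constant
  for +1/−2 scoring. An earlier guess of 0.1 under-estimated the
  expectation: a 100-random-fragment run produced a chance hit at a
  nominal e-value of 5e-6.
- **Word size 11 and identity floor 0.85** are the package's documented
  defaults for a ~2%-divergent repeat family; the source analysis states
  only "BLAST" and the e-value, so these are choices, not inferences.
- **Ties** are broken deterministically everywhere: strand + before −,
  lexicographic consensus id, leftmost subject position; equal-score
  merges take the longest overlap; equal-support junction clusters take
  the smallest coordinates; tied insert interpretations take the
  rightmost donor (the maximal donor arm), then the leftmost acceptor.
- **Unmerged pairs** are carried as two independent fragments rather than
  as a linked pair; a junction spanned only by the unsequenced middle of
  a long fragment is therefore invisible, which is conservative.
- **Retention evidence**: isoforms are reconstructed from explicit
  retention patterns (or full retention by default). Assembling
  full-length evidence sequences from overlapping reads is not
  implemented; with junction support in the single digits, a greedy
  assembly would mostly manufacture chimeras, so patterns must come from
  the caller or from clone-level sequences.
- **Degenerate inputs**: zero-length regions are dropped from the
  annotation (which is how the two-segment 135 + 188 wheat-style
  architecture is built); templates shorter than the read length are
  skipped with a warning; an empty consensus set, invalid error rates,
  negative lengths and unknown pipeline parameters raise immediate
  errors.

## Known limitations

- The read taxonomy assigns each fragment to the family of its primary
  chain; fragments fusing two families are AMBIGUOUS rather than
  inter-element fusion calls.
- Junctions whose arms sit entirely inside long microhomology runs, and
  short-variant reads whose retained piece is followed by fewer than
  11 anchorable nt, are intrinsically unidentifiable at the read level;
  they are excluded by the identifiability definition above, not
  recovered.
- The e-value model treats the search as ungapped at uniform
  composition; with heavily skewed composition the significance
  threshold would shift.
- Strand assignment of junctions reflects fragment orientation and is
  biologically meaningful only for orientation-preserving libraries (the
  generator's default).
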