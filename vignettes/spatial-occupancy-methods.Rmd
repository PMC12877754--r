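---
title: "Methods: spatial chromatin-accessibility analysis on Hi-C embeddings"
author: "GaudiHiC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial chromatin-accessibility analysis on Hi-C embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GaudiHiC)
```

## The question the pipeline answers

Chromatin accessibility (ATAC-seq) tells us *which* regulatory sequence is
open; Hi-C tells us *where* that sequence sits in the folded chromatin of a
locus. GaudiHiC combines the two for a ~1-Mb window around a gene of
interest: it embeds the window's Hi-C contact structure in the plane,
paints accessibility onto the embedding ("Gaudí plots"), and then asks
which transcription-factor (TF) binding motifs fall in accessible,
high-importance sequence that is *spatially* — not merely linearly — close
to the gene's transcription start site (TSS). Run for two conditions
(e.g. vehicle vs. a pathway inhibitor), the differential report counts
family-level motif occupancy changes, such as AP1 (FOS/JUN) sites closing
while TCF/LEF sites open.

## Model and procedure

1. **Binning and balancing.** Intrachromosomal contacts over the window
   are binned at 5 kb (a 1-Mb window gives 200 bins) and ICE-balanced:
   per-bin biases $b_i$ are iterated as
   $b_i \leftarrow b_i\sqrt{s_i/\bar s}$ (with $s_i$ the current row sum
   over unmasked bins) until row sums are uniform; output values are
   $x_{ij}/(b_i b_j)$, rescaled so the mean unmasked row sum is 1, and the
   rescaling is folded back into the biases so
   $\text{balanced}_{ij}\, b_i b_j$ reproduces the raw input exactly.
   All-zero rows (unmappable bins) are masked throughout.

2. **Interaction graph.** Balanced interactions are transformed
   $w = \log_{10}(1 + x)$ and the top 20% of the nonzero off-diagonal
   upper-triangle entries become graph edges with distance $d = 1/w$.
   The $+1$ matters: balanced values are mostly below 1, so a bare
   $\log_{10}$ would give non-positive weights and negative or infinite
   "distances". Counting only *nonzero* entries keeps the selected edge
   number independent of sparsity artifacts. Backbone edges between
   genomically consecutive bins are always added (distance = the median
   selected distance), which keeps the polymer chain connected — without
   them an isolated bin would make the layout undefined. Ties at the
   selection cutoff break lexicographically on $(i, j)$, so output is
   deterministic.

3. **Layout.** Edge distances are completed to all pairs by Dijkstra
   shortest paths, and the Kamada–Kawai stress
   $\sigma(X)=\sum_{i<j}\big(\lVert x_i-x_j\rVert - D_{ij}\big)^2/D_{ij}^2$
   is minimized. We run SMACOF majorization (weights $1/D_{ij}^2$, a
   monotone descent on exactly this stress) from two fixed starts — a
   circle in genomic order with radius $\overline{D}$, and classical MDS —
   and refine the better warm start with L-BFGS using the analytic stress
   gradient. Majorization alone converges slowly near the optimum (on a
   200-bin matrix, 1000 iterations still sat ~3% above the refined
   stress); the two-phase scheme is faster *and* better, and every step is
   deterministic, so layouts are byte-identical across runs. Layouts are
   defined up to rigid motion; all downstream quantities (distances,
   areas, neighborhoods) are invariant to it.

4. **Gaudí geometry.** The spatial unit is the *mean interbin distance*:
   the average layout distance between genomically consecutive unmasked
   bins. Each bin gets a buffer disc of radius 1.5× that unit,
   approximated by a regular 64-gon (area deficit 0.16%, below every
   tolerance used), and its Voronoi cell, realized exactly as the
   intersection of perpendicular-bisector half-planes against all other
   generators (Sutherland–Hodgman clipping; only generators within twice
   the buffer radius can cut the disc, so the clip set is small). The
   occupancy polygon is disc ∩ cell. We read the published "buffer zone
   (1.5 the mean interbin distance)" as a *radius*; the diameter reading
   would halve all areas and make adjacent bins non-contiguous in typical
   layouts, contradicting the contiguous worm-like plots the construction
   is named for. A ring of 36 dummy nodes at 4× the layout's centroid
   radius closes unbounded Voronoi cells; at that distance a dummy's
   bisector can never cut a buffer disc, so dummies only close the
   diagram. Exactly coincident bins (degenerate toy layouts) are separated
   by a deterministic jitter of $10^{-6}$× the mean interbin distance
   rather than erroring.

5. **Signal and neighborhoods.** Accessibility is averaged per bin
   (uncovered bases count 0, full bin width as denominator) and colors the
   polygons after clipping to the 1st–99th percentile. The TSS
   neighborhood is every unmasked bin within 3.0× the mean interbin
   distance (inclusive) of the TSS-containing bin — the dashed circle in
   the rendered plots.

6. **Contribution filtering and motif scanning.** Per-base contribution
   scores (from a sequence-to-accessibility model such as ChromBPNet;
   always an *input* here) are thresholded at their 90th percentile
   computed across the whole analysis window (type-7 sample quantile,
   `>=` non-strict), per condition; retained bases inside the
   neighborhood's bins are merged into maximal intervals. The reference
   distribution is a documented choice — the source procedure does not
   state whether "top 10%" is per-window or genome-wide; per-window keeps
   the filter self-contained. Retained intervals are scanned with PWMs on
   both strands using log2 odds against the background; a window is a hit
   when its score reaches 0.8× the motif's maximum attainable log-odds.
   A fraction-of-maximum threshold is deterministic and directly
   verifiable against a brute-force scorer, which the tests do
   exhaustively; `N` bases contribute zero log-odds so flanking `N`s
   neither create nor destroy hits. Minus-strand hits are scored on the
   reverse complement and reported in plus-strand coordinates.

7. **Family counting and the differential report.** Hits are mapped to TF
   families (FOS/FOSB/FOSL1/FOSL2/JUN/JUNB/JUND → AP1;
   TCF7/TCF7L1/TCF7L2/LEF1 → TCF/LEF; unmapped motifs keep their own name)
   and overlapping hits of one family collapse to a single site, so
   paralogous motifs at one footprint are not double-counted — occupancy
   statements like "six AP1 motifs" are family-level. The report gives
   per-family counts per condition, their difference, and per-site
   condition membership, so "open in A, closed in B" sites are listable.
   The enrichment helper (`motifEnrichment`) is a deliberate
   simplification of MEME-style enrichment: a two-sided Fisher exact test
   on sequence-level hit presence with Benjamini–Hochberg q-values, ranked
   by ascending q then descending sample odds ratio, keeping the q < 0.01
   filtering convention available to users.

## Coordinates

All coordinates are 0-based half-open, the convention of BED/bedGraph and
binned matrix tooling. Published region strings (commas, en-dash) parse
verbatim; whether such printed coordinates are 0- or 1-based is
conventionally ambiguous, and we fix the half-open 0-based reading — at
5-kb resolution the one-base difference cannot move a bin assignment.
`asGRanges()` converts to the 1-based closed convention of
*GenomicRanges*.

## The synthetic-data generator

The generator produces inputs with the statistical structure the analysis
assumes, so every stage — and the end-to-end differential comparison — is
testable without external data:

* **Hi-C**: $\mu_{ij} = \text{depth}\cdot(1+|i-j|)^{-\alpha}\cdot
  \text{boost}^{[\text{same TAD}]}$ with $\alpha = 1$ (the canonical
  contact-decay slope), boost 3 (strong enough that TAD co-membership
  dominates the spatial neighborhood, the property the analysis exploits),
  depth 100, optional Poisson noise; symmetric by construction.
* **Genome**: i.i.d. background at GC 0.4 with consensus sites planted
  verbatim (reverse-complemented on the minus strand). Chance occurrences
  of a planted consensus elsewhere in the window are scrubbed by a
  deterministic single-base substitution: a 7-mer recurs by chance ~15
  times per Mb, and the generator's ground truth is only a truth if
  exact-consensus hits coincide with it.
* **Tracks**: accessibility is basal 1 plus 5 over peak bins with
  zero-truncated Gaussian noise applied per 100-bp chunk (coverage noise
  is locally correlated); contributions are footprint-shaped tent bumps of
  apex ~1 spanning each visible site ±5 bp (per-base values are exact
  per-base integrals of the tent, so a bump integrates to
  $(\text{width}+10)/2$), over a low-amplitude half-normal background
  (scale 0.01). The background reflects that sequence models assign every
  base a small nonzero contribution; it also keeps the 90th-percentile
  threshold meaningful — on a strictly sparse track the threshold would be
  0 and the "top 10%" filter would retain the entire window. Setting
  `contribBackground = 0` recovers the strictly sparse track.
* **Condition pair**: one shared genome; six AP1 sites flank locus E
  (three accessible only in condition A, three in both conditions) and
  five TCF/LEF sites flank locus L (accessible only in condition B), each
  site footprinted only in the conditions where it is accessible. The
  default 1-Mb window at 5 kb with four equal TADs reproduces the
  vehicle-versus-treatment design this package targets: AP1 6 → 3 and
  TCF/LEF 0 → 5. Defaults scale with the window (TAD boundaries at
  quarters, loci at the centers of the first and last TAD).

What the generator does *not* emulate: read-level noise, fragment-level
Hi-C artifacts, nucleosome structure, genome-wide peak landscapes,
correlated bias between conditions. Passing tests therefore demonstrate
that the *pipeline logic* recovers planted spatial-occupancy differences
under the stated noise, not that the method's biological conclusions
transfer to any particular dataset.

## Numerical choices and degenerate inputs

* ICE tolerance $10^{-8}$ relative on row-sum uniformity, 200 iterations;
  non-convergence is a warning plus a flag, not an error. All-zero
  matrices error.
* Quantile type 7 (R's default) for the contribution threshold; with
  scores $1..10$ the 0.9 quantile is 9.1, so exactly the top base is
  retained.
* JASPAR pseudocount 0.01 per cell: keeps log-odds finite without
  distorting informative positions; MEME probabilities get the same
  regularization.
* The layout's brute-force oracle (tests): for up to 4 nodes the global
  stress minimum is bounded by a 0.05-step lattice search with node 0
  pinned at the origin and node 1 on the positive x-axis; the embedding
  must come within 5% of it. The 4-node lattice (~10^9 configurations) is
  precomputed by `inst/scripts/layout_lattice_oracle.py` on the fixed-seed
  suite and frozen in the tests; 2- and 3-node cases are searched live.
* Problem sizes in the routine test and acceptance runs: the study-scale
  window (1 Mb, 200 bins) for end-to-end recovery over 20-seed suites
  (zero-noise and Poisson + track noise at 0.2× peak height), 200-kb
  windows for file round-trip tests, 100×100 matrices for balancing
  properties, 200 random kilobase sequences × 5 random PWMs for the
  scanner equivalence.

## Known limitations

* Single intrachromosomal window per run; no genome-wide tiling or
  interchromosomal contacts.
* The Voronoi construction is 2D by design — it visualizes the embedded
  contact topology, not 3D structure.
* PWM hits use a fraction-of-maximum threshold, not a p-value calibrated
  to background composition; for strongly skewed backgrounds the
  family-count comparison is still valid (both conditions share the
  threshold) but absolute counts shift with the threshold.
* `motifEnrichment` tests sequence-level presence, ignoring hit
  multiplicity per sequence.
* Binary formats (.cool, bigWig) are not read directly; export them to
  COO/bedGraph text first.
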