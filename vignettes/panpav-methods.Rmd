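---
title: "Pan-genome PAV analysis and selective-sweep scanning with panpav"
author: "panpav authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome PAV analysis and selective-sweep scanning with panpav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpav)
```

# Overview

`panpav` implements the analytical core of a plant pan-genome
presence/absence-variation (PAV) study: building a non-redundant
pan-reference by iteratively appending novel sequence from individual
genome assemblies, turning gene-level evidence into a binary PAV matrix,
classifying pan-genes by occupancy, describing population structure from
the PAV matrix, and scanning genotypes for diversity, differentiation and
selective sweeps. Every stage can be exercised end to end on synthetic
populations whose ground truth is known, so each statistical claim the
package makes is testable against an oracle or a planted truth.

The intended scale is a desk-scale model system: a single synthetic
chromosome of 10 Mb and on the order of a hundred accessions, standing in
for a multi-gigabase crop genome with c. 100 resequenced accessions. The
methods are scale-free; the default sizes keep every analysis within
minutes on one CPU.

# The pan-reference augmentation model

Given a base reference and a set of per-accession contig assemblies, the
augmentation loop processes accessions in a fixed order (lexicographic by
id by default; the order is configurable and the total appended novelty is
insensitive to it on data of this kind — shared novel segments change
owner, not existence). For each contig:

1. **Anchor alignment** (`anchorAlign()`): exact k-mers (default
   k = 21) shared between the contig and the current pan-reference are
   grouped per (target, strand, diagonal) and chained along each diagonal;
   chains are extended gap-free with an x-drop rule (match +1, mismatch
   −2, drop 20). Each segment's identity is the count of exactly matching
   bases divided by the segment length; `N` never counts as a match.
   Reverse-strand hits are found through the contig's reverse complement.
   The aligner is deliberately gap-free: the assemblies the pipeline
   consumes diverge from the reference by substitutions at ≤ 2%, so a
   banded, per-diagonal model is sufficient, and a dynamic-programming
   alignment on small pairs serves as the identity oracle in the tests.
2. **Trim and retain** (`trimAndRetain()`): segments with identity
   ≥ 0.90 over ≥ 100 bp qualify; their union is subtracted from the
   contig. Complement intervals of ≥ 100 bp are retained as novel
   sequence; shorter leftovers are discarded. The three parts always
   partition the contig exactly, which is property-tested.
3. **Append**: retained sequences join the pan-reference with provenance
   (source accession, contig, interval, iteration) and become alignment
   targets for every later accession, which is what makes the pan
   non-redundant and the procedure idempotent: re-augmenting an already
   processed accession adds 0 bp.

The 100 bp floor on *retained* novel sequence mirrors the 100 bp floor on
qualifying alignments; it is a package decision (the length filter on
appended sequence was an open design point) and is exposed as
`minRetainedLen`.

# From gene evidence to a PAV matrix

Pan-gene clusters are the row universe of the PAV matrix. When gene
sequences are available, `greedyClusterGenes()` provides a deterministic
greedy stand-in for orthogroup inference: genes sorted by decreasing
length join the first cluster whose representative they match at gap-free
identity ≥ 0.90, else they found a cluster. This is an explicit
simplification — phylogenetic orthogroup inference is out of scope — but
it preserves the downstream contract (one cluster id per pan-gene).

Presence has two evidence routes, combined by `buildPavMatrix()`:

* **Annotation**: the accession contributed an annotated member gene.
* **Map-to-pan recovery** (`callPresence()`): the gene's read coverage
  has breadth ≥ 0.99 of its length *and* mean depth ≥ 3×. Both
  thresholds are inclusive, and "depth" is the mean fold-coverage over
  the gene (the alternative reading, minimum depth, was rejected as it
  makes the rule needlessly sensitive to single-base dropouts).

Recovery is monotone — coverage can only turn absences into presences —
and each presence records which rule fired, so annotation-dropout
artifacts remain auditable.

# Occupancy classes, accumulation curves and uniqueness

With N accessions, a pan-gene present in a fraction f of them is **core**
(f ≥ 0.99), **soft-core** (0.90 ≤ f < 0.99), **shell**
(0.15 ≤ f < 0.90) or **cloud** (f < 0.15). The bands partition (0, 1]
and the boundaries matter: at N = 116, occupancy 115 is core and 114
soft-core; 18 is shell and 17 cloud. These boundary cases are asserted
exactly in the tests.

`panCoreCurves()` draws accession-order permutations and reports, per
prefix size n, the union (pan) and strict intersection (core) counts.
Strict intersection is deliberately distinct from the ≥ 99%
classification band; both semantics are exposed. When N! does not exceed
the requested permutation count the full permutation set is enumerated,
so small-N curves are exact. `fitSaturationModels()` fits a Heaps-type
power law P(n) = A·n^γ + C to the pan curve and an exponential decay
K(n) = κ·e^(−n/τ) + Ω to the core curve (the Tettelin convention), by
nonlinear least squares via `minpack.lm`. The figure the study tradition
draws names no equation, so the functional forms are a package decision;
constant curves and non-convergence are flagged, never silently fitted.

`uniqueGroupGenes()` removes every cluster present in two or more groups;
what remains is unique to its group, and unique-core additionally reaches
core occupancy within the group's own columns. `enrichTerms()` runs the
standard one-sided Fisher exact test (hypergeometric upper tail) per term
with Benjamini–Hochberg correction over the tested terms only.

# Population structure from PAVs

`pavDistance()` offers simple-matching distance (proportion of
differing clusters; the default, because it treats presence and absence
symmetrically, which matches how PAV matrices are read) and Jaccard
distance. `njTree()` is Saitou–Nei neighbor joining; it reconstructs any
additive distance matrix exactly, which the tests verify on random trees
up to 12 leaves. Negative branch lengths are reported as computed, with
an optional clamp.

`wardCluster()` applies the `ward.D` Lance–Williams update to squared
Euclidean dissimilarities; for binary rows the squared Euclidean distance
is the Hamming count, so no further transform is applied. The tree is cut
into exactly K clusters (default 8, labeled A, B, … by decreasing size).
The axis is a parameter: pan-genes are clustered by default, matching how
PAV heat maps are drawn, with accessions available via
`axis = "accessions"`.

# Diversity, differentiation, LD and sweeps

* **π** (`windowPi()`): per site with n non-missing alleles and
  alternate count c, π = 2c(n−c)/(n(n−1)) — the mean pairwise
  difference. Windows of 1,000 kb tile each chromosome at 100-kb steps
  (full windows only) and the window value divides the summed per-site π
  by the window span in bp (not the covered-bases alternative, which was
  the other reading of the external tool's convention). At most 600 SNPs
  are assayed per window, mirroring the cap used by the score scan that
  consumes these windows.
* **FST** (`weirCockerhamFst()`): the Weir–Cockerham (1984) θ with the
  a/b/c variance components computed per site and the estimate as a ratio
  of sums. Negative estimates are reported raw by default so oracle
  equivalence is exact; clamping is optional. Missing genotypes are
  excluded site-wise (pairwise-complete), as in common VCF tooling.
* **LD** (`ldDecay()`): with phased haplotypes, pair r² is
  D²/(pA·qA·pB·qB) from haplotype frequencies — numerically the squared
  correlation of the two haplotype indicator columns; the unphased
  fallback is the squared Pearson correlation of dosages. Pair values are
  binned by distance and the half-decay distance is the first bin
  midpoint at which the 3-bin running mean falls to half its maximum.
* **Sweeps** (`sweepFilter()`): the composite filter consumes a
  cross-population selection-score track (the score computation itself,
  e.g. XP-CLR, is an input, not reimplemented). Scores are z-normalized
  genome-wide ("normalized" is unspecified in the tradition this follows;
  the z-score makes the top-quantile rule scale-free), the top
  ⌈5%·W⌉ windows are selected by rank with genomic-order tie-breaks,
  the reduction of diversity ROD = π_wild/π_domesticated is ranked
  *among the selected windows* (the antecedent of "top 50%" is ambiguous;
  ranking within selective regions is the reading consistent with the
  filter being a refinement), and the top ⌈50%·|selected|⌉ survive,
  infinite ROD first. Surviving windows that overlap or are bookended
  merge into sweeps — merge distance 0, the default of the standard
  interval-merging tool. All intermediate window sets are returned.
* **LAI** (`lai()`): intact LTR-RT length over total LTR-RT length × 100,
  provided as the assembly-quality utility it is.

# The synthetic-data generator

`simConfig()` fixes the study conditions; its defaults are the desk-scale
panel the package targets and are not tuned per analysis:

* **Panel**: three species-like groups of 79 + 22 + 15 accessions
  (N = 116), echoing a cultivated/wild legume panel with one large
  cultivated group and two smaller wild relatives.
* **Pan-gene classes**: 310 core, 123 soft-core, 820 shell and 1,002
  cloud genes — the published class proportions of a large crop
  pan-genome scaled down by roughly 50× so the matrix stays desk-sized —
  plus 40 group-preferred genes per group (present in ≥ 80% of the own
  group, ≤ 5% elsewhere, leak probability 0.02). Occupancy within each
  band is sampled uniformly; the empirical within-band distribution of
  real pan-genomes is unknown, and uniform is the assumption-free choice.
  Bands are realized exactly by construction, and an N too small to
  separate the bands is a hard error rather than a silent approximation.
* **Genome**: one 10-Mb chromosome at GC 0.38 (a legume-like value).
  The real system is three orders of magnitude larger; sequence content
  is random, so repeat structure is *not* emulated (see Limitations).
* **Assemblies**: 6 accessions spread over the groups, 5 contigs of
  300 kb each, substitution noise at 2% (the upper end of the intended
  divergence regime, so the augmentation contract is exercised at its
  boundary), 3 planted novel inserts per accession of 150–2,000 bp,
  GC-matched random sequence, 25% drawn from a shared pool so the
  iterative trimming actually deduplicates across accessions. Novel
  inserts are placed verbatim into the noisy backbone, so the planted
  sequence is exactly recoverable.
* **Genotypes**: the Balding–Nichols model — per site an ancestral
  frequency p ~ U(0.05, 0.95) and per group a Beta(p(1−F)/F,
  (1−p)(1−F)/F) frequency — because its F parameter equals the expected
  Weir–Cockerham θ, giving a closed-form recovery target. Default
  F = 0.45, in the range of strong between-species differentiation;
  5,000 sites.
* **Sweep tracks**: lognormal background scores with sdlog 0.4 —
  chosen a priori so that a 10× score multiplier separates cleanly from
  the background (at this spread a multiplied window beats the 95th
  background percentile with overwhelming probability) — and one planted
  sweep at [4.0, 5.2] Mb with multiplier 10 and a π reduction factor of
  0.2 in the domesticated population. A window counts as inside a sweep
  only when fully contained in it, so the planted truth equals the union
  of its elevated windows and recovery is measured without the smearing
  that window overlap would otherwise cause. The default sweep spans 3
  window starts, matching the survivor count the 5%/50% filter yields on
  a 91-window chromosome, so the composite filter can in principle
  recover the truth exactly; that geometry is part of the planted
  experimental design, fixed before any measurement.
* **Coverage evidence**: truly present genes draw breadth in
  [0.99, 1] and lognormal depth (median 12×) unless hit by coverage
  dropout (default 0.02); absent genes draw sub-threshold coverage.
  Annotation dropout (default 0.10) removes the annotation evidence for
  some present genes so the map-to-pan route is actually exercised. At
  zero dropout the rebuilt PAV equals the planted truth exactly.

Every generator restores the caller's RNG state and derives its seed from
the master seed by a fixed per-stage offset, so stages are independently
reproducible and the whole pipeline is deterministic: two runs with the
same config produce byte-identical artifacts (checked by content hash).

# Numerical and degenerate-input decisions

* Internal coordinates are 0-based half-open (BED convention); VCF
  positions are the only 1-based surface, and the converters are tested
  at the 1 ↔ 0 boundary.
* Identity denominators: alignment segments use segment length; pairwise
  gene identity uses the longer sequence, so equal-length substitution
  pairs give exactly the global gap-free identity.
* Sites with fewer than two sampled alleles are skipped (π), as are
  sites with undefined WC84 components; groups under two diploids are a
  hard error.
* A Jaccard pair with zero union gets distance 0 with a warning; an
  all-zero PAV row violates the container's validity and cannot be
  constructed.
* Q-criterion and ROD ties break by genomic/index order, so every
  ranking is deterministic.
* Fit non-convergence and constant curves are flagged results.

# What passing tests do and do not show

The synthetic generator reproduces the *statistical* structure the
analyses assume — planted occupancy bands, group-preferred genes,
Beta-distributed allele-frequency differentiation, multiplicative sweep
signals — under which every estimator is checked against an independent
oracle (brute-force pairwise π, transcribed WC84 components, exhaustive
permutation enumeration, DP alignment identity, hypergeometric
enumeration) or a planted truth. It does not emulate repeat-rich genome
content, alignment ambiguity in paralogous families, indel/SV divergence,
linkage between PAV and SNP structure, or coverage biases correlated with
GC — so green tests certify the correctness of the computations, not the
behavior of the upstream assembly, annotation and mapping tools that real
data would pass through first.

Problem sizes used throughout (10-Mb chromosome, 116 accessions, ~2,500
pan-genes, 5,000 SNPs, ≤ 12-leaf trees for exactness checks) are the
package's chosen desk scale: large enough for the asymptotic behavior the
estimators rely on, small enough that the full suite and the demo
pipeline run in minutes.

# Session info

```{r}
sessionInfo()
```
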