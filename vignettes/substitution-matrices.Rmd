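---
title: "Building and benchmarking substitution matrices with submatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and benchmarking substitution matrices with submatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(submatkit)
```

## The estimation model

An amino-acid substitution matrix scores the replacement of residue *i* by
residue *j* in an alignment as a log-odds ratio: how much more (or less)
often the pair is observed in alignments of related proteins than expected
if residues paired at random. submatkit implements the classical BLOSUM
recipe on top of *family-weighted* substitution counts:

1. **Observations.** Each data point is an *ungapped pair block*: two
   equal-length residue strings whose columns are believed to correspond.
   Blocks come either from column-comparable sequences or from rigid-body
   superposition of two protein chains (see below).
2. **Family weighting.** A family with $n_k$ members contributes
   $\binom{n_k}{2}$ pairs. Each pair is weighted
   $w_k = 2 / (n_k (n_k - 1))$, so every family deposits the same total
   mass per alignment column regardless of its size. Without this, one
   100-member family would outweigh hundreds of small ones.
3. **Counting.** Every aligned column $(x, y)$ adds $w_k$ to the unordered
   pair mass $f_{xy}$. The matrix `f` is stored symmetrically; its total
   mass equals the weighted number of columns.
4. **Log-odds.** Unique-entry masses are normalized to observed pair
   frequencies $q_{ij}$; background frequencies are
   $p_i = q_{ii} + \sum_{j \ne i} q_{ij}/2$; expected frequencies are
   $e_{ii} = p_i^2$ and $e_{ij} = 2 p_i p_j$; the score is
   $s_{ij} = \tfrac{1}{b}\log_2(q_{ij}/e_{ij})$ with $b = 0.5$ bits per
   unit by default — *half-bit* scores, i.e. $2\log_2(q/e)$ — rounded to
   the nearest integer.

Pairs with sequence identity above 62% are dropped before counting
(`identityThreshold = 0.62`). Highly similar pairs carry almost no
substitution signal but large absolute counts; the threshold keeps the
counts from being dominated by near-duplicates. Identity is measured on a
global affine-gap alignment (BLOSUM62, gap open 10, extend 1) as identical
columns over all alignment columns.

### Numerical choices

* **Pseudocount.** The classical recipe is silent about never-observed
  pairs. By default a pseudocount of $10^{-6}$ of the total mass is added
  to every unique cell *within the observed sub-alphabet* before
  normalization; residues that never occur at all keep a score of 0 rather
  than receiving an artifact of the pseudocount's tiny marginals. Setting
  `pseudocount = 0` makes zero cells a hard error naming the offending
  pair. Because the default scales with the total, the estimate is exactly
  invariant to duplicating the data.
* **Rounding** is half-away-from-zero (so $-4.64 \to -5$), not banker's
  rounding, which keeps results platform-independent.
* **$n_k$** counts the family members available to pairing (those with
  structures, in structure mode), not the post-filter pair count; the build
  report records both pair tallies so the alternative is easy to audit.
* Families contributing no retained pairs are excluded from the family
  count.

## Structure-derived correspondences

When family members carry 3D chains, residue correspondences are extracted
by iterative superposition-reassignment:

1. **Seeding** with a global *sequence* alignment under the identity (unit
   1/0) matrix — deliberately not BLOSUM62, so no substitution-matrix
   knowledge leaks into the structural stage that is supposed to produce
   independent evidence.
2. **Kabsch superposition** (closed-form least-squares rotation +
   translation, reflection-corrected) on the current pairs.
3. **Re-pairing** as mutual nearest alpha-carbon neighbors within a
   proximity threshold (default 5 Å, the conventional CA contact scale),
   pruned to the longest strictly-monotone subsequence (ties broken toward
   the smaller summed distance). Monotone pruning encodes the assumption
   that correspondences respect sequence order — the blocks are ungapped.
4. Repeat until the pair set is stable, at most 20 iterations. An empty
   correspondence is a legitimate outcome for unrelated chains.

The scheme is a self-contained structural aligner designed for the
alpha-carbon traces this package works with. External aligners can be used
instead: their correspondences are imported from a TSV of index pairs.

## Alignment engine

Global (Needleman–Wunsch/Gotoh) alignment with affine gaps, written in
C++. A gap of length $L$ costs $\mathrm{GOP} + (L-1)\,\mathrm{GEP}$ by
default; engines disagree on this convention, so the alternative
$\mathrm{GOP} + L\,\mathrm{GEP}$ is available as a flag (and is the form
under which the engine is cross-checked against
`Biostrings::pairwiseAlignment` in the test suite). Terminal gaps are
penalized. Traceback ties break deterministically: diagonal, then gap in
the second sequence, then gap in the first. Fractional penalties (the
benchmark grid uses half-integer gap extension steps) are handled by exact
integer scaling: the smallest integer factor making every score and
penalty integral, under which optimal scores scale exactly.

## Benchmarking toolkit

* **Q-score** — of the residue pairs co-aligned in a reference MSA, the
  fraction also co-aligned in the test MSA. **TC-score** — the fraction of
  reference columns reproduced exactly (including which rows are gapped);
  all-gap reference columns are excluded from the denominator. TC ≤ Q by
  construction; both are invariant to all-gap columns and row order.
* **Realignment** uses a progressive aligner: UPGMA guide tree over
  pairwise identity distances, then profile–profile global alignment with
  mean sum-of-pairs column scoring (gap–residue pairs score 0). It is
  deterministic and pluggable — an external aligner can be injected into
  the gap-penalty grid search.
* **Gap-penalty grid search** scans GOP 0–10 (step 1) and GEP 0–5 (step
  0.5) by default, scoring mean Q and TC over the references after
  stripping and realigning; exact ties resolve to the smaller GOP, then
  GEP.
* **Homology evaluation** scores all sequence pairs, flags same-superfamily
  pairs, and computes ROC AUC (Mann–Whitney, ties at half credit) and PR
  AUC (step-wise average precision — the conservative interpolation).
* **Nearest-neighbor retrieval** consumes precomputed per-protein vectors,
  retrieves each entry's L2 nearest neighbor, scores entry × class cells by
  the indicator that the retrieved neighbor carries the class, and reports
  one micro-averaged one-vs-rest AUC.

## Matrix analytics

```{r analytics}
b62 <- standardMatrix("BLOSUM62")
evolutionaryDistance(b62)
matrixCorrelation(unitMatrix(1, 0), b62)
```

*Evolutionary distance* is $|\overline{s_{ii}} / \overline{s_{i \ne j}}|$,
the mean match score over the mean mismatch score in absolute value —
larger for matrices tuned to more divergent sequences. It is invariant to
uniform rescaling and undefined when the mean mismatch score is exactly
zero (unit matrix 5/0). *Correlation* between two matrices vectorizes all
400 entries by default; this whole-matrix convention is the one that
reproduces the standard published correlation-to-BLOSUM62 figures (72%
for the 1/0 unit matrix, 84% for PAM250, 98% for BLOSUM80), so it is the
default, with the 210-unique-entry vectorization available as an option.
*Identical fraction* and PCA operate on the 210 unique entries, since the
redundant lower triangle carries no extra information.

## What the synthetic data emulate — and what they do not

The generators provide every fixture with known ground truth:

* `substitutionProcess(d, p)` defines the per-column joint pair
  distribution $Q = (1-d)\,\mathrm{diag}(p) + d\,p p^T$ — a direct
  interpolation between perfect conservation ($d=0$) and independence
  ($d=1$) whose marginals equal $p$ at every divergence. The interpolation
  (rather than a rate-matrix exponential) is chosen precisely because its
  log-odds target is available in closed form (`analyticLogOdds`), making
  *exact* parameter-recovery tests possible. Members are drawn
  conditionally on a latent ancestor column, so a member pair follows the
  process composed with itself: divergence $1 - (1-d)^2$, returned by
  `pairProcess()`.
* `simulateStructurePair()` lays a chain on a regular helical curve with
  exactly 3.8 Å between consecutive alpha-carbons, then derives a homolog
  by a contiguous deletion, Gaussian coordinate noise, and a random rigid
  motion, recording the true mapping.
* `simulateReferenceMsa()`, `simulateLabeledScores()` and
  `simulateVectors()` provide reference alignments, score sets and vector
  clusters with recorded truth.

These fixtures validate the *machinery*: that counting, weighting,
filtering, estimation, superposition and scoring do what they claim. They
do not emulate indel evolution, phylogenetic correlation between family
members, domain architecture, or the residue composition of real protein
families — so passing recovery tests demonstrates correctness of the
pipeline, not that a matrix built from any particular structure collection
will match a published one.

## Problem sizes and defaults used by the test suite

Parameter recovery runs 50 simulated families (25 two-member, 25
three-member, 2 000 columns each) at divergence 0.55, giving ≥ $10^5$
weighted columns — enough for the rounded estimate to sit within ±1 of the
analytic target at every unique entry. The convergence analysis uses 24
families and 50 random subsets per size; exhaustive alignment oracles run
on all 36 length combinations up to 6 over a 4-letter alphabet. These
sizes were chosen as the smallest at which the statistical guarantees are
comfortably non-marginal.

## Known limitations

* The structural aligner is sequence-order-dependent by design; it will
  not find circular permutations or order-independent superpositions.
* The progressive realigner has no iterative refinement; on divergent,
  gap-rich references its Q-scores trail dedicated MSA engines.
* Exact all-vs-all scoring is quadratic in the number of sequences;
  the homology benchmarking is meant for dataset sizes where exact search
  is feasible.
* `identicalFraction` is defined for integer matrices only; real-valued
  matrices should be compared by correlation.
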