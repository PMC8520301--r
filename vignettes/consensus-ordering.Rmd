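---
title: "Consensus ordering of pan-genome alignment blocks: model and methods"
author: "pancora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ordering of pan-genome alignment blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancora)
```

## The problem

A pan-genome is the union of the sequence content of all individuals
(cultivars, accessions, strains) of a species. Declaring one assembly
*the* reference biases every downstream comparison, so pancora builds a
reference-agnostic representation instead: the output of a multiple
whole-genome aligner (XMFA alignment blocks, or a Mauve-style backbone
coordinate table) is reduced to blocks, and the blocks themselves become
the coordinate system.

With $n$ input genomes, each alignment block is classified by how many
genomes it occurs in:

* **core (C)** — present in all $n$ genomes;
* **dispensable (D)** — present in at least 2 and at most $n-1$;
* **unique (U)** — present in exactly one genome.

Part of the literature treats unique content as a special case of
dispensable content; pancora keeps the three-way partition (and
`blockSummary(x, mergeUnique = TRUE)` recovers the two-way convention).
Each genome is then rewritten as an ordered sequence of signed block
occurrences, and — restricted to core blocks — as a signed permutation
$\sigma^i$ of the core block identifiers $\{1, \dots, m\}$, one
permutation per chromosome.

## The consensus ordering

The backbone of the representation is the *consensus ordering*
$\sigma^*$: a single linear order of the core blocks minimizing

$$\sum_{i=1}^{n} L(\sigma^i, \sigma^*)$$

where $L$ is the unit-cost Levenshtein (edit) distance over block-id
symbols. This is the median-permutation problem, NP-complete in
general, so pancora uses a greedy approximation:

1. Maintain a set of linear orderings (paths), initially empty. Seed a
   new path from the lowest-numbered unassigned core block (the seed is
   arbitrary in principle; the lowest id makes runs reproducible).
2. At a path terminus, rank the unassigned neighbors of the terminus
   block by adjacency frequency across the $n$ genomes. Left- and
   right-side adjacencies are pooled for the ranking; only candidates
   observed on the side being extended are eligible there, and a genome
   traversed right-to-left contributes reversed, sign-flipped
   adjacencies. With top frequencies $f_1 \ge f_2 \ge f_3$ (absent
   candidates count as frequency 0):
   * a three-way tie $f_1 = f_2 = f_3$ among three or more candidates
     suspends the side — the region is too variable to order;
   * otherwise the most frequent candidate is appended (frequency ties
     break toward the lower block id), signed by the majority relative
     orientation.
3. Each path is extended left to exhaustion, then right to exhaustion;
   when no path can grow, the next unassigned block seeds a new path.

The result partitions the core blocks into one or more paths; a single
path per chromosome is the ideal outcome.

## Refinement: orientation, mis-joins, coordinates

Each path and its reversal (order reversed, signs flipped) are aligned
locally against every genome's core permutation with a Smith–Waterman
scheme over block symbols: +1 for an aligned block, −1 for a gap or a
mismatch. The orientation with the higher summed best score is kept
(exact ties keep the forward path, for determinism).

A path whose summed best score falls below a threshold — by default 80%
of the attainable maximum $\sum_i \min(|path|, |\sigma^i|)$ — is
treated as a mis-join: it is cut at the boundaries of its best-aligned
central span into a central piece and up to two overhangs, and every
piece is re-oriented and re-checked until all pieces pass. Pieces of
one or two blocks are finalized outright: under ±1 scoring a mis-join
inside them is not detectable, and this guarantees termination since
pieces are strictly shorter. The "attainable maximum" reading makes
the 80% threshold scale-free; it is exposed as `threshold_frac`.

Finalized paths are anchored by a majority vote on their best
alignments: the anchor is the median over genomes of the bp start of
the aligned span (the median is well-defined for even $n$ and robust to
a single outlier placement), the chromosome group is the most common
aligned sequence name, and paths are laid out cumulatively in (group,
anchor) order. Each consensus block's length is the median of its
per-genome interval lengths.

Edit distances compare unsigned symbols by default — the permutation
formalism above is unsigned, while blocks are oriented — and every
alignment/distance routine takes `signed = TRUE` to make orientation
part of the comparison.

## Rendering: tracks and dot-plots

For visualization each (genome, core block) pair gets exactly one
rendering class, computed per chromosome from the longest
order-preserving chain between the genome's core order and the
consensus ranks: contiguous reversed-orientation, rank-decreasing runs
may sit on the chain as inverted segments. On-chain blocks with
matching orientation are *collinear* (light blue), on-chain inverted
segments are *inverted* (pink), off-chain blocks — including
cross-chromosome placements — are *translocated* (dark blue);
dispensable blocks are green and unique blocks red. A chromosome whose
reversed reading carries a heavier chain is classified in that
direction. Chain computation is a weighted longest-increasing-
subsequence with leftmost tie-breaking, so it is deterministic.

BED output is BED6+1 (chrom, start, end, name = class label, score,
strand, RGB string), one track per genome plus a consensus track. The
gap-aligned variant lays all tracks on a common virtual axis where
every core block occupies the same interval in every genome; the
stretch after each core block holds each genome's D/U content packed
left-to-right and is sized to the largest requirement across genomes.
Dot-plots place one point per (genome, core block) at the consensus
and genome midpoints; the per-genome y offset (2% of the consensus
span per genome index) only prevents overplotting.

## The synthetic generator and what it does (not) emulate

`scenarioConfig()` / `generateScenario()` build pan-genomes with known
truth: an ancestral ordering of core and dispensable blocks, uniform
dispensable presence patterns over 2..$n-1$ genomes (the simplest model
exercising every classification branch), per-genome unique insertions,
uniform block lengths (500–2000 bp at desk scale), and planted
inversions, translocations and variable-region shuffles. Events
reverse/move the actual signed occurrences, so strand handling is
exercised end to end. `divergentPair()` mirrors the effect of adding a
wild relative to a cultivated panel: the extra genome misses a quarter
of the core blocks (demoting them to dispensable), carries extra unique
content and a heavily shuffled order, and a quarter of the blocks split
in two in all genomes, emulating alignment fragmentation.

The generator emulates block structure, not sequence: there is no
nucleotide-level evolution, no repeat content, no aligner noise, and
block boundaries are exact. Passing tests therefore validate the
block-level algorithms under planted truth; they do not validate an
upstream aligner's behavior on real assemblies.

```{r example}
scn <- generateScenario(presetScenario("inversion", seed = 5))
res <- runPanGenome(scn$blockset)
res$summary
table(res$rendering$color_class)
```

The six inverted records above are exactly the planted 6-block
inversion in genome 2.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; XMFA and backbone
  files are 1-based inclusive at the file boundary (BED, the dominant
  sink, is 0-based half-open).
* All tie-breaks are fixed: lowest block id for seeds and frequency
  ties, forward for orientation ties, leftmost-start-then-shortest-span
  for alignment ties, leftmost chain in rendering. Two runs on the same
  input produce byte-identical TSV/BED outputs.
* Fewer than three distinct neighbor candidates pad the frequency list
  with zeros, so two tied candidates still extend (the three-way-tie
  rule only fires with three or more present candidates) and a single
  candidate extends unconditionally.
* Empty inputs degrade gracefully: a genome with no blocks yields an
  empty (warned) sequence, a sequence with no core blocks an empty
  permutation, an empty permutation set an empty consensus.
* Problem sizes: presets use 4 genomes with 40 core / 12 dispensable /
  4 unique-per-genome blocks; oracle comparisons enumerate
  permutations at $m \le 7$, $n \le 5$. These sizes exercise every
  code path while keeping exact enumeration feasible.

## Known limitations

* An inversion that spans a chromosome *end* can defeat the greedy
  consensus: at the permutation boundary the only adjacency evidence
  comes from the inverted genome, the path absorbs the minority
  junction, and the refinement step cannot split it because the
  minority-matching span is the path's own best central alignment. The
  interior inversions typical of real data (centromeric and
  mid-chromosome events) are recovered exactly; the boundary case is
  inherent to the greedy-plus-threshold design.
* The 80% mis-join threshold is applied to the summed score across
  genomes; a per-genome variant is a straightforward extension but is
  not the default.
* The backbone dialect has no sequence field, so it is restricted to
  one sequence per genome; multi-chromosome data go through XMFA.
* Exact median computation is exposed only as a toy-scale reference
  (`exactMedianOrdering`); at genome scale only the greedy path is
  practical.
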