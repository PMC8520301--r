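# pancora

Reference-agnostic pan-genome representation: block classification,
consensus ordering of core blocks, and synteny visualization tracks.

## The problem

Comparative analyses of many assemblies of one species usually pick one
of them as *the* reference, which biases every downstream comparison.
`pancora` instead consumes the output of a multiple whole-genome aligner
(XMFA alignment blocks, or a Mauve-style backbone coordinate table) and
builds a representation in which the blocks themselves are the
coordinate system:

* each alignment block is classified by occupancy over the *n* genomes —
  **core** (all *n*), **dispensable** (2 to *n*−1), or **unique**
  (exactly 1);
* restricted to core blocks, every chromosome of every genome is a
  signed permutation σⁱ of the core block ids {1, …, m};
* the **consensus ordering** σ\* is a linear order of the core blocks
  minimizing Σᵢ L(σⁱ, σ\*), with L the Levenshtein distance over block
  symbols — the median permutation. That problem is NP-complete, so
  σ\* is approximated greedily from adjacency frequencies, then refined:
  each candidate path is oriented and screened by local alignment
  (match +1, gap/mismatch −1) against every genome, paths scoring below
  80% of the attainable maximum are split at their best-aligned central
  span, and the pieces are ordered by a majority vote (median) of their
  per-genome anchor coordinates.

The result feeds per-genome and consensus BED6+1 tracks (plain or
gap-aligned, with core blocks colored light blue / dark blue / pink for
collinear / translocated / inverted, dispensable green, unique red) and
dot-plot point sets in which inversions appear as anti-diagonal runs and
translocations as isolated points.

A synthetic-data module generates pan-genomes with planted truth
(classes, consensus, inversions, translocations, variable regions,
divergent added genomes) and serializes them in the same XMFA/backbone
dialects, so the whole pipeline is testable without any download.

## Worked example

A four-genome panel with 40 core, 12 dispensable and 4 unique-per-genome
blocks and one planted 6-block inversion in genome g2:

```r
library(pancora)
scn <- generateScenario(presetScenario("inversion", seed = 5))
res <- runPanGenome(scn$blockset)

res$summary
#>         class count     bp   fraction
#> 1        CORE    40 198428 0.73322396
#> 2 DISPENSABLE    12  35509 0.13121157
#> 3      UNIQUE    16  23885 0.08825899

res$consensus
#> ConsensusOrdering: 40 core blocks in 1 path(s), 0.050 Mbp

table(res$rendering$color_class)
#> core_collinear  core_inverted
#>            154              6
```

The 40 core blocks cover 73.3% of the summed genome length and collapse
into a single consensus path. Of the 160 (genome, core block) pairs,
exactly the 6 occurrences of the planted inversion in g2 are classified
inverted — they show up pink in `writeBedTracks()` output and as an
anti-diagonal run in `dotplotPoints()` / `plotDotplot()`.

With file input instead of an in-memory block set:

```r
paths <- writeScenario(scn, "fixtures")      # XMFA + backbone + catalog
res <- runPanGenome(paths[["xmfa"]], "xmfa", paths[["catalog"]],
                    outdir = "out", gap_aligned = TRUE)
```

which writes `summary.tsv`, `consensus.tsv`, `bed_plain/` and
`bed_gap_aligned/` track sets, `dotplot.tsv` and a run log. A thin CLI
wrapper with `run` and `synth` subcommands is installed at
`inst/scripts/pancora-cli.R`.

## Layout

* `R/` — classes (`GenomeCatalog`, `PanBlockSet`, `ConsensusOrdering`),
  I/O, classification, consensus, refinement, tracks, synthesis, oracles.
* `src/` — Rcpp kernels: edit distance, Smith–Waterman over block
  symbols, exhaustive alignment and exact-median enumeration.
* `vignettes/consensus-ordering.Rmd` — the model, parameters, numerical
  choices and known limitations.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
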