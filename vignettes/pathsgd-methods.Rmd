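---
title: "Path-guided SGD layout: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-guided SGD layout: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsgd)
```

## The model

A variation graph embeds genomes as paths: ordered series of steps, each
step visiting a node on its forward or reverse strand. Any two steps on
one path are separated by a *nucleotide distance* (nd) — the difference of
their cumulative offsets along the path — and this is the only distance
PG-SGD ever uses. The layout objective is the classic MDS stress idea:
place nodes so that Euclidean layout distances (ld) between node ends match
the nucleotide distances the genomes dictate. Because terms are sampled
from paths, the quadratic all-pairs distance computation of conventional
stress layouts never happens; the path index answers every distance query
in O(1) from per-path prefix sums of node lengths.

One SGD *term* is built as follows:

1. an anchor step is drawn uniformly from all steps of all paths (paths
   therefore weigh by their step counts, so shared, repetitive nodes get
   proportionally more attention);
2. a partner step is drawn on the same path — uniformly with probability
   `flip_probability`, otherwise at a Zipf-distributed rank distance in
   step space, in a random direction (reflected at the path ends);
3. each step contributes the node end nearer the other step in path
   coordinates (ties take the sequence-start end), so adjacent nodes are
   chained end-to-start; `nd` is the coordinate difference of the chosen
   ends. An anchor that samples itself (guaranteed on one-step paths)
   yields a term joining the node's two ends at `nd` = node length — this
   is what gives each node its drawn extent.

The update with weight `w = 1/max(nd,1)^2`, rate `mu = min(eta * w, 1)`
and displacement `r = mu * (ld - nd)/2` moves both ends along the line
joining them. `mu <= 1` guarantees the update never overshoots
(`|ld' - nd| <= |ld - nd|`), which is the property that makes uncoordinated
parallel updates benign.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `iter_max` | 30 (1D) / 100 (2D) | iterations | sorting converges much faster than drawing; both leave margin at desk scale |
| `min_term_updates` | 10 × total steps | terms/iteration | every step participates ~10× per iteration in expectation |
| `eta_max` | (max path length)² | nt² | makes `mu = 1` for even the farthest sampled pair at t = 0: first iterations perform global moves |
| `eta_min` (= `epsilon`) | 0.01 | nt² | final rates `mu ≈ 0.01/nd²` vanish: last iterations only refine locally |
| Zipf `theta` / `window` | 0.99 / 10000 | — / steps | a long-tailed law: mostly local pairs, with regular long-range draws; window capped at path steps − 1 |
| cooled `theta` / `window` | 2.0 / 100 | — / steps | sharply concentrated small rank distances, enhancing local linearity/planarity |
| `flip_probability` | 0.5 | — | half of the updates use uniform partners — global information that keeps long linear structures from collapsing |
| `cooling_start` | 0.5 | fraction | the skewed law takes over after half the iterations |
| `sigma` | 1.0 | nt | Y-noise of the `order_*` 2D initializations; tiny relative to X so the init is almost 1D |
| `threads` | 1 | workers | >1 enables lock-free HOGWILD-style updates |

The annealing schedule is geometric,
`eta_t = eta_max * (eta_min/eta_max)^(t/(iter_max-1))`, hitting both
endpoints exactly and the geometric mean at the midpoint.

The reference ecosystem for these graphs fixes the sampling *mechanism*
(uniform anchor, Zipf/uniform partner, flip, cooling) but no constants;
the Zipf exponents, windows, iteration counts and the step-space (rather
than nucleotide-space) interpretation of Zipf ranks are this package's
declared choices, fixed once and exposed in the configuration objects.

## Numerical choices and degenerate inputs

* `nd = 0` terms (coincident path positions, e.g. abutting node ends) are
  kept: with `w = 1` they strongly co-locate the pair, exactly what a
  chained layout needs.
* `ld = 0` (coincident points) would make the update direction undefined;
  a pseudo-random unit direction is drawn from the term's own RNG stream,
  never a fixed axis (which would bias layouts), so runs stay reproducible.
* In 1D a node is a single coordinate, so a term joining a node to itself
  is a no-op and is skipped; stress evaluation in 1D likewise drops
  self-pair terms as unmeasurable.
* A 1D layout and its mirror image have identical stress; the engine
  canonicalizes the sign after the run (coordinates are negated if they
  anti-correlate with the first path's own order — the same convention as
  fixing a PCA axis sign). Canonicalization is skipped when nodes are
  frozen, since flipping would move pinned coordinates.
* Frozen (`path_fixed`) nodes are simply never written to; their partner
  still moves, so the free part of the graph arranges itself around the
  pinned reference.
* Single-threaded runs are bit-deterministic for a fixed seed (one
  xoshiro256** stream per iteration). Multi-threaded runs interleave
  atomically-written updates without locks and are only statistically
  reproducible; tests therefore compare multi-worker runs by stress, not
  coordinates.

## What the synthetic graphs emulate — and what they do not

The generators produce the structural motifs a pangenome layout engine
must survive: linear chains (trivial embeddings), biallelic SNP and indel
bubbles (multiple paths, locally divergent coordinates), inversions
(reverse-strand traversal and implicit reverse complements), tandem
repeat loops (nodes with multiple path visits, where no exact Euclidean
embedding exists), and scrambled node ids (the unsorted input of the 1D
sorter). Sequences are uniform ACGT because only node *lengths* enter the
algorithm; node lengths are drawn uniformly from 1–32 bp, the scale of
typical variation-graph segmentation.

A green test on these fixtures establishes that the machinery optimizes
its objective on every motif — not that the layout of a real gigabase
pangenome is biologically informative. Real graphs add scale, nested and
overlapping variation, and highly repetitive regions whose step
multiplicity dominates runtime; none of that is represented here.

## Acceptance-test conventions

Two conventions used by the acceptance suite are worth stating plainly.
First, two stress values below 1e-4 are treated as "both converged to the
exact embedding": a normalized stress of 1e-4 corresponds to a typical
relative residual of 1%, below which the ratio of two stochastic runs is
numerically meaningless. Second, the comparison against the brute-force
full-batch SGD-MDS oracle is a quality gate on the sampled algorithm, so
it is one-sided: landing *below* the oracle's stress passes.

## Known limitations

* The path index is plain dense arrays; memory is linear in total steps
  with no succinct compression, which is the right trade-off at package
  scale but not at whole-human-pangenome scale.
* Uniform anchor sampling weights paths by step count, not nucleotide
  length; short, step-dense paths get proportionally more updates.
* No GPU path, no cache-blocking of the coordinate vector, and no binary
  layout formats; outputs are TSV and SVG only.
* GFA support is deliberately GFA1 S/L/P with blunt (0M) overlaps and
  integer segment names; W-lines and rGFA tags are rejected.
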