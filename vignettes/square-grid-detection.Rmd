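---
title: "Detecting square-grid structure in neuronal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting square-grid structure in neuronal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridness)
```

## The problem

Animal neuronal networks are usually summarized as small-world graphs:
triangle-rich, short-path architectures. Regular lattice-like arrangements —
in particular a tiling of *square grids*, where the minimal unit is the
four-node cycle C4 — are a qualitatively different organization, analogous to
the spatially periodic firing of entorhinal grid cells. `gridness` quantifies
how much of a connectivity network is organized as overlapping square-grid
neighborhoods, and where.

No single graph metric isolates this pattern. Transitivity detects triangular
grids, not square ones; spectral bipartivity peaks at 1 for square grids but
also for stars and other bipartite shapes. The detector therefore combines
several metrics, each acting as a filter.

## The metric suite

All metrics are computed on undirected simple graphs (directed synapse
records are collapsed; weights are ignored — the method is purely
topological).

* **Transitivity** `T = 3·(triangles) / (triads)`, a triad being two edges
  sharing a vertex. `T = 0` for any square lattice; `T` around 0.42-0.49 for
  triangular lattices, which is what this filter excludes. Triad-free graphs
  are assigned `T = 0`.
* **Square clustering** (Lind–González–Herrmann): per node, the realized
  fraction of potential four-cycles through its neighbor pairs; averaged over
  nodes for a graph-level value. It decreases with lattice size (0.28 for a
  3×3 lattice down to 0.16 for 9×9) and is carried in reports as a verifier
  rather than used as a band.
* **Spectral bipartivity** `b = Σ cosh(λ) / Σ exp(λ)` over adjacency
  eigenvalues: the fraction of closed-walk weight on even-length walks.
  `b = 1` exactly for bipartite graphs (all square lattices); `b → 0.5` for
  large complete graphs. Computed by dense symmetric eigendecomposition —
  windows and components here are at most a few hundred nodes — with the
  exponentials rescaled by the spectral radius so dense graphs cannot
  overflow, and clamped at 1 against rounding noise (the ratio is ≤ 1
  analytically).
* **Average shortest path length** over unordered pairs, by breadth-first
  layering. It is defined only on a connected graph; disconnected input is an
  explicit error rather than a silent per-component average, because the
  choice would change sigma.
* **Small-world sigma** `σ = (C/C_rand) / (L/L_rand)`, with `C` the mean
  local triangle clustering and `L` the average path length, normalized
  against degree-preserving random references (Maslov–Sneppen double edge
  swaps). `σ > 1` indicates small-world architecture; the band `σ ≤ 0.5`
  excludes it.

### Sigma conventions

Three numerical decisions matter:

* **Triangle-free graphs score `σ = 0`** by convention. For a square lattice
  both `C` and `C_rand` can be 0, a 0/0 form; defining `σ = 0` whenever
  `C = 0` is the only consistent reading that gives ideal square grids a
  sigma of exactly 0. (In the degenerate converse — `C > 0` but every
  reference triangle-free — sigma is `+Inf`, which simply fails the band.)
* **References**: 10 random references per evaluation, each produced by 5
  accepted swaps per edge; swaps that would create self-loops or parallel
  edges are rejected and retried, with an attempt cap so saturated graphs
  terminate. A complete graph admits no legal swap and is returned unchanged,
  which makes `σ(K_n) = 1` exactly. If a reference comes out disconnected,
  its path length is taken on its largest component.
* **Seeding**: every consumer of randomness derives its sub-seed
  deterministically from one master seed (per-window, per-reference), so a
  whole scan or sweep is bit-reproducible from a single integer.

## Calibration on reference models

`run_sweep()` generates six model families and tabulates per-model min/max
metric ranges:

| model | sizes | parameters |
|---|---|---|
| complete | 9–27 nodes | — |
| square lattice | 3×3 … 9×9 (9–81 nodes) | — |
| triangular lattice | m = n = 3 … 11 (10–78 nodes) | — |
| random (Erdős–Rényi) | 9, 18, 27 | P ∈ {0.4, 0.5} |
| preferential attachment | 9, 18, 27 | M ∈ 3…6 |
| small world (Watts–Strogatz) | 9, 18, 27 | k ∈ {4, 6}, p ∈ {0.1, 0.5} |

Choices made where the design was open:

* Square lattices are square-shaped (3×3 through 9×9), matching the 9-to-81
  node range for grid-like models.
* Triangular lattices use the standard row construction (alternating
  diagonals); square-shaped instances m = n = 3…11 step the node count from
  10 to 78 across the same range.
* The non-grid families are represented at n = 9, 18 and 27, three sizes
  spanning their 9-to-27 range; stochastic cells are replicated over 20
  derived seeds, and ranges are pooled over cells and replicates.
* `k` "4 to 6" for the ring model is realized as {4, 6}: odd k has no ring
  construction, and we reject it explicitly rather than round silently.
* Random graphs at low P can come out disconnected; they are kept, with
  path-based quantities evaluated on the largest component.

`derive_criteria()` turns the sweep into the classification bands and
validates them: the square-grid row must pass every band, and the complete
and triangular rows must each fail at least one. The calibrated defaults in
`grid_criteria()` are transitivity ∈ [0, 0.20], bipartivity ∈ [0.80, 1.0],
sigma ∈ [0, 0.50], component size ≥ 36. Band endpoints are inclusive — the
search is deliberately non-conservative, aimed at finding departures from
the ideal grid rather than only perfect ones.

## The sliding-window scan

`grid_scan()` runs the full detector:

1. **Component filter.** Only the largest connected component is analyzed,
   and only if it has at least 36 neurons (smaller samples cannot support
   the metrics).
2. **Windows.** For every node, the closed 2-hop neighborhood — the node,
   its neighbors, and their neighbors — induces a window subgraph, which is
   scored with the metric suite. Windows under 4 nodes (smaller than the C4
   motif) are unflaggable rather than errors.
3. **Classification.** A window is flagged when all three bands pass.
4. **Overlap clustering.** Flagged windows sharing at least one node are
   chained into clusters; clusters need ≥ 2 windows. Isolated flagged
   windows are reported separately as weak evidence — non-contiguous
   square-grid windows are not considered evidence of a larger arrangement.
5. **Score.** The square-grid-ness of the component is the fraction of its
   nodes covered by the union of the clusters, reported as a whole percent.

The "share ≥ 1 node" overlap rule is our formalization of the qualitative
overlap requirement; the original procedure verified overlap visually.
`export_graphml()` replaces that by-eye step with a GraphML file in which a
boolean `grid_member` attribute marks cluster nodes for any graph viewer.

```{r example}
lat <- gen_square_lattice(6, 6)
grid_scan(lat, seed = 1)

grid_scan(gen_complete(12), grid_criteria(min_component_nodes = 10), seed = 1)
```

## The hybrid fixture and what tests show

`gen_hybrid()` plants a square lattice inside a background graph (by default
an Erdős–Rényi graph) connected by a small number of bridge edges, and
returns the planted node set. This emulates one feature of real connectomes
— a regular patch embedded in irregular surroundings — and the recovery
tests show the detector finds essentially the whole planted lattice across
seeds.

It does not emulate other features of real data: populations of neurons at
grid vertices, degree heterogeneity of real neuropil, or sampling truncation
at region boundaries. Passing recovery tests therefore demonstrates
correctness of the machinery, not field performance.

One behavior of the method is worth stating plainly: a sparse random
background (edge probability around 0.15) has expected transitivity near
0.15 — *inside* the transitivity band — and its 2-hop neighborhoods are
often near-bipartite and triangle-poor. Whole background windows can
therefore genuinely satisfy all three bands, so scans of sparse irregular
networks include false-positive clusters. This is inherent to the
non-conservative criteria, not a numerical artifact: a reference
implementation of each metric assigns such windows the same in-band values.
Interpreting scan output on sparse networks should lean on the flagged
clusters' structure (e.g. the GraphML export), not the score alone.

## Problem sizes and limitations

The test suite and examples run the sweep at the sizes above (635 graphs,
seconds of runtime) and scans of networks up to a few hundred nodes. Dense
eigendecomposition and matrix-based path layering scale comfortably to the
~1000-node components typical of per-region connectome files; much larger
components would need sparse methods. Sigma is the dominant cost (10
randomized references per window); triangle-free windows short-circuit to
`σ = 0`, which makes lattice-like regions cheap and irregular regions the
slow case.

Known limitations: only square-grid patterns are sought (no triangular or
hexagonal modes); no statistical null model is attached to the score — the
evidence argument is contiguity of overlapping windows, not significance;
and edge weights and directionality are deliberately discarded.
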