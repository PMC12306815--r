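---
title: "Sketch-guided force-directed layout: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-guided force-directed layout: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchlayout)
```

`sketchlayout` turns a freehand raster sketch into placement constraints
for a force-directed graph layout. This vignette explains the method stage
by stage, the assumptions it rests on, the parameters that matter, and the
design decisions taken where more than one reasonable choice existed.

## 1. From pixels to a segment chain

**Binarization.** Sketches are assumed dark-on-light; a pixel is
foreground when its intensity is below `threshold` (default 128 on the
0–255 scale; `"otsu"` selects the threshold automatically from the
histogram, and `invert = TRUE` handles light-on-dark input). Foreground
components smaller than `min_speck` pixels (default 5) are discarded
before thinning: a minimal noise guard, since stray specks would otherwise
each become a spurious polyline.

**Thinning.** The skeleton is computed with the classic two-subiteration
Zhang–Suen scheme iterated to a fixed point: a pixel is deleted when its
8-neighbourhood has 2–6 foreground members, exactly one 0→1 transition
around the cyclic neighbour ring, and the subiteration's two neighbour
products vanish. Two properties are load-bearing for the rest of the
pipeline and are enforced/tested explicitly:

* *idempotence* — the output is unchanged by further passes, by
  construction;
* *component preservation* — the textbook rules can erase a component
  entirely (a 2×2 block, or any blob that collapses to one, is deleted in
  a single simultaneous pass). `thin()` therefore keeps the first pixel of
  any component that a pass would erase completely. A filled disc thus
  thins to a single point rather than to nothing, and the 8-connected
  component count of input and skeleton always agree.

**Spur pruning.** Thinning a wobbly stroke leaves short branch spurs.
`prune_spurs()` deletes endpoint pixels (exactly one 8-neighbour)
simultaneously for `spur_length` rounds (default 10 px). Closed loops have
no endpoints and are untouched; open strokes lose at most `spur_length`
pixels at each genuine end, which is negligible at 512×512.

**Tracing.** Polylines are extracted by endpoint-seeded 8-connected
walking rather than by region splitting: walks start at endpoint pixels,
continue until no unvisited neighbour remains, and leftover pixels (pure
cycles, branches cut off at junctions) seed further walks. Two details
matter in practice:

* Zhang–Suen represents some diagonals as 4-connected staircases, so a
  raw degree ≥ 3 does *not* indicate a branch. A diagonal neighbour that
  touches an orthogonal candidate is deferred (the walk reaches it through
  the orthogonal pixel), and branching is instead detected by the crossing
  number — three or more 0→1 transitions around the neighbour ring.
* At a true junction the walk keeps the branch that best preserves the
  current heading (largest dot product with the incoming direction; ties
  prefer orthogonal steps, then the lower pixel index). Remaining branches
  become separate polylines, with a warning: branching sketches are only
  best-effort supported (see §6).

A skeleton consisting only of isolated pixels yields an empty list with a
warning rather than an error.

**Simplification.** Each polyline passes through a radial-distance filter
and then Ramer–Douglas–Peucker. The documented contract is that every
original point lies within `simplify_tolerance` (perpendicular distance)
of the simplified polyline. The two passes compound — a point dropped by
the radial pass lies near a kept point that RDP may later remove — so the
budget is split internally: one third to the radial pass, two thirds to
RDP, which makes the combined bound provable while still flattening
hand-drawn wobble (a unit-amplitude noisy line simplifies to its two
endpoints at the default tolerance). The default tolerance is 5 px at
512×512, scaled proportionally with the image diagonal for other
resolutions.

**Chain assembly.** Simplified polylines are merged greedily: starting
from the first, the polyline whose endpoint lies nearest to a free chain
end (within `offset_threshold`, default 5 px) is attached, reversed if
needed; the touching endpoints are snapped to their midpoint and made
bit-identical, so the shared-endpoint invariant holds exactly. The chain
is closed when the two final free ends also fall within the threshold.
Leftover polylines that cannot attach mean the sketch is branching or
disconnected — an error, since the method needs one continuous stroke.
Tiny fragments (shorter than the larger of the offset threshold and the
simplification tolerance) are discarded before assembly with a warning;
they are spur remnants, not stroke.

## 2. Node–line mapping

The graph is treated as undirected here; self-loops are dropped. Nodes of
degree one are excluded in a *single* pass over the original degrees —
iterative 2-core peeling would empty path-shaped graphs entirely, which is
why it is only available behind `prune_graph(iterative = TRUE)`. A graph
whose pruned core is empty (a single edge, a perfect star with one leaf…)
is an error unless `keep_all_nodes = TRUE`.

**Closed sketches → cycle heuristic.** Finding the longest cycle is
NP-hard, so a DFS from each not-yet-visited node tracks the longest cycle
closed by a back edge to the current stack; DFS from visited nodes is
skipped, and total neighbour examinations are capped at
`50·(|V|+|E|)` to keep the stage near-linear. The cycle is accepted only
when `|C| ≥ τ` with `τ = ceiling(tau_factor · sqrt(|V′|))`,
`tau_factor = 2` by default: a ring C_n is accepted for every n ≥ 9, while
incidental short cycles (two triangles joined by a bridge, say) are
rejected. Start order is a seeded shuffle, so results are deterministic
per seed. Every returned cycle is verified to be a simple cycle before
use.

**Everything else → BFS double sweep.** If the chain is open *or* no
sufficiently long cycle exists, a BFS from a seeded-random node of the
largest component finds a farthest node (maximum hops, ties to the
smallest node id); a second BFS from there yields the node order and its
tree parents. Neighbours are explored in sorted-id order for determinism.
Nodes outside the largest component are left unconstrained and reported —
disconnected input is not really supported (§6).

**Apportionment.** Segment `i` of length `d_i` receives
`k_i = d_i·|seq|/D` nodes, made integral by the largest-remainder method
(floors, then one extra to the largest fractional remainders, ties to the
lower segment index). This conserves `Σk_i = |seq|` exactly, which the
suite checks over a thousand random chain/sequence pairs. Nodes are dealt
in traversal order, and `target_positions()` spaces each segment's `k_i`
nodes at interior fractions `j/(k_i+1)` — these anchors initialize the
layout and define the reference shape for the fidelity score. The cycle's
first node is assigned to the chain's first segment; no rotational
alignment between cycle and chain is attempted (a deliberate
simplification — the refinement and the similarity-invariant fidelity
measure both absorb a global rotation).

The traversal parent map `P` drives constraint generation: the cycle
predecessor in the cycle case, the second-sweep BFS-tree parent in the
path case. The BFS-tree choice (rather than "previous node in the visit
order") keeps every relative constraint anchored to an actual graph edge.

## 3. Constraint generation

Each segment is classified by slope: horizontal when `|Δy/Δx| < ε`,
vertical when `|Δx/Δy| < ε` (the two tests are mutually exclusive for
`ε < 1` since the ratios multiply to 1), otherwise diagonal by the sign
pair. `ε = 0.2` by default — generous enough to absorb hand wobble. Image
coordinates have y growing downward, so `Δy > 0` reads top-to-bottom, and
this convention propagates through the layout and the SVG output.

For each mapped node `v` with predecessor `q = P(v)`, the label of *v's*
segment decides the constraints (one horizontal or vertical relative for
axis-aligned labels, one of each for diagonals); a segment's node sequence
additionally becomes one alignment group when the segment is axis-aligned
and carries at least two nodes. Alignment groups are *not* merged across
consecutive same-label segments — each stays scoped to its segment.

Closed chains can fold labels back onto themselves, so a relative
constraint may contradict earlier ones. Policy: first come, first served.
A constraint is dropped (with a warning) when it duplicates an earlier
one, when it would close a directed cycle on its axis, or — at layout
time, after alignment groups are merged — when it becomes infeasible at
the merged level. The exported JSON
(`relativePlacementConstraint` / `alignmentConstraint`) follows the option
schema of fCoSE-style constrained layout engines, so generated constraints
can drive that ecosystem unchanged.

## 4. Constrained layout

The embedder is a standard spring model: attraction `d²/k` along edges,
repulsion `k²/d` between pairs, ideal edge length `k = 50` px. Per-node
displacement is capped by a temperature decaying linearly from `k/2` to
1 px over `iterations` (default 500). Repulsion is exact up to 1500 nodes
and grid-approximated above (nodes repel occupied-cell centroids,
count-weighted, with exact forces inside the own cell) — this keeps the
whole pipeline near-linear at the few-thousand-node scale. Coincident
nodes receive a small deterministic index-based nudge; the layout is
reproducible bit-for-bit for a fixed seed.

**Initialization.** Mapped nodes start at their anchors — the anchors
*are* the sketch, so this both encodes the user's intent and speeds
convergence. Pruned degree-one nodes start at a small seeded offset from a
neighbour; any remaining nodes at seeded uniform positions in the anchor
bounding box.

**Projection.** After each force step the constraints are re-imposed
exactly. Alignment groups on one coordinate are merged into super-nodes
(union-find); each super-node takes its members' mean coordinate (the
alignment snap), and relative constraints become `gap` edges (default
10 px) between super-nodes, enforced in one forward pass over a
topological order of the merged DAG, then recentred so the mean
displacement is zero. An earlier implementation used per-constraint
Gauss–Seidel repair sweeps; on ~1000-node constraint chains those
propagate one constraint per sweep and need O(n²) sweeps to converge,
which made full satisfaction unreachable at scale — the topological pass
is exact in one O(V+E) sweep and has identical semantics (alignment
first, then ordered relative repairs). After the final iteration every
relative constraint and every alignment group is satisfied to residual
≤ 1e−6, which the suite asserts on every end-to-end fixture.

**Refinement.** `refine_iterations = 30` unconstrained low-temperature
iterations relax the drawing; each node's total displacement from its
constrained position is capped at `refine_cap = k/2`. Constraints may be
slightly violated afterwards — that is the point (the fully constrained
result can look rigid) — and the report and fidelity are recomputed so the
trade-off is visible. `refine_iterations = 0` is the exact identity.

**Fidelity.** Both the achieved positions and the anchors are centred and
unit-normalised; the optimal rotation-plus-scale (Procrustes, reflections
excluded via the determinant sign) aligns them, and the score is one minus
the residual sum of squares — equivalently the squared sum of the
sign-corrected singular values of the cross-covariance. It is invariant
under similarity transforms of the positions and agrees with symmetric
Procrustes from `vegan` (which permits reflections) whenever the optimal
transform is orientation-preserving; the suite cross-checks this.

## 5. The synthetic fixtures

`render_sketch()` draws five canonical strokes (line, L, rectangle,
circle, zigzag) dark-on-white at a chosen stroke width, with freehand
wobble emulated by per-vertex Gaussian displacement (`sigma = jitter`
pixels) applied before rasterization — this is exactly the kind of
deviation the slope threshold, the simplification tolerance and the
endpoint offset threshold are designed to absorb. The exact jittered
polyline is attached as ground truth. `make_graph()` produces rings,
paths, random-attachment trees and tree-plus-extra-edges sparse graphs
(always connected), deterministic per seed.

What the fixtures do *not* emulate: pressure/width variation along a
stroke, anti-aliased or textured pens, multi-stroke sketches, pen lifts,
and scanned-paper noise beyond isolated specks. Passing tests therefore
demonstrate the pipeline's behaviour on clean single-stroke input of the
intended kind, not robustness to arbitrary scanned drawings.

Problem sizes used by the suite and the acceptance script — chosen as
representative of the method's intended small-to-medium scale: 20 random
binary shapes for the thinning properties, 100 random polylines for the
simplification bound, 1000 random cases for apportionment conservation,
rings C9–C60 for cycle recovery with exhaustive-search cross-checks on
connected graphs of ≤ 10 nodes, end-to-end fixtures of 12–60 nodes, and
one 2000-node / 2512-edge sparse graph against a 512×512 sketch.

## 6. Known limitations

* **One continuous stroke.** Branching or disconnected sketches are
  rejected at chain assembly (or handled best-effort with warnings during
  tracing). Supporting branch structures would require a tree-shaped
  chain model and a different mapping.
* **Curves are polygonalized.** A circle becomes ~20 short segments;
  direction labels around such a loop are mostly diagonal, so circles are
  enforced through relative constraints alone. Fidelity remains high, but
  the drawn shape is a polygon, not an arc.
* **Uniform-degree assumption.** Proportional apportionment assumes nodes
  deserve roughly equal arc length; hub-heavy graphs will crowd their
  hubs' neighbourhoods. Degree-aware distribution is out of scope.
* **No rotation optimization** between cycle and chain (see §2): the
  mapping starts at the chain's first segment, which is arbitrary for a
  closed sketch.
* **Refinement may violate constraints** by design, bounded by
  `refine_cap`; use the pre-refinement result (`$constrained`) when exact
  satisfaction matters.
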