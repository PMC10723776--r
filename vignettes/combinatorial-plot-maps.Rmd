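---
title: "Combinatorial plot maps: model, operations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial plot maps: model, operations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agromap)
```

## The model

agromap represents an agroforestry plot as a **2D combinatorial map**. The
atomic object is the *dart*: an oriented half-edge running between two nodes
and carrying its origin coordinates (plot-local Cartesian metres, x east, y
north, origin at the south-west corner) plus a free property bag. Two
operators act on darts:

* `beta1`, a **permutation**: the next dart along the border of the same
  face. Iterating `beta1` from any dart walks the complete border of the
  face it belongs to (`orbit_face()`).
* `beta2`, an **involution**: the oppositely oriented partner dart across
  the shared edge, so `beta2(beta2(d)) = d` and `beta2(d) != d`. An edge of
  the subdivision is exactly a `beta2` pair.

Faces are plot elements — understory vegetation strips, crop alleys, tree
crowns, and the explicit *outside* face representing the world beyond the
plot. Requiring the outside face makes `beta2` total: every border of the
plot is an interface like any other, which matters agronomically (edge
effects, exchanges with the surroundings) and mathematically (all orbits
become cyclic, and the Euler relation V − E + F = 2 holds with F counting
the outside face).

Nodes are not stored: a node is an orbit. Two node-like orbits are provided
and they differ deliberately:

* `orbit_node(d)` alternates `beta1` then `beta2` starting with `beta1` and
  collects all darts incident to the *head* node of `d`. This is the
  traversal useful for data exchange at a junction (on an open map it
  returns the truncated chain). These orbits overlap between neighbouring
  nodes, so they cannot be used for counting.
* `orbit_vertex(d)` iterates the vertex rotation σ(d) = beta1(beta2(d)),
  collecting the darts *emanating from* the origin node of `d`. These
  orbits partition the dart set; the number of distinct orbits is the node
  count V used in the Euler check.

The operator order in `orbit_node()` was chosen to reproduce the standard
worked chain on the open two-triangle map (start at dart 1: beta1 gives 2,
beta2 gives 4, beta1 gives 5, then the involution is unset and the walk
stops), rather than the opposite composition order, which does not.

### Hierarchy: holes

A face may contain *holes*, each filled by an embedded face: a tree is a
face inside its strip's hole. A hole is a clockwise cycle of darts that
belong to the parent face and are `beta2`-sewn to the embedded face's
border. The definition is recursive, one level per scale. Orbits stay
within a level: the hole cycle and the parent's outer border are distinct
`beta1` cycles, so walking a strip's border never wanders into its trees.
Per level the Euler relation holds in the form V − E + F = 2 per connected
component; a strip with k trees contributes k hole/filling components, each
a closed 2-face sub-map with characteristic 2.

### The dual

The dual map models interactions: each face becomes a node, each dart an
oriented relation from its own face to its `beta2` partner's face. The dual
shares the primal's darts and `beta2`; its successor is the vertex rotation

    beta1_dual(d) = beta1(beta2(d))

Note that the beta tables cannot be literally "the same" in the dual — with
unchanged tables the orbits, hence the faces and nodes, would be unchanged
too. With the vertex-rotation successor the dual's face orbits are the
primal's vertex orbits (|faces(dual)| = |vertices(primal)|), dual nodes are
primal faces, and applying the construction twice gives
`beta1(beta2(beta2(d))) = beta1(d)`: the primal is recovered exactly. The
dual is a *lazy view*, recomputed on demand by `build_dual()`, so edits can
never desynchronize the two representations. It is built per hierarchy
level (top level by default); containment (strip contains tree) is exposed
through `face_parent()`/`face_holes()`, not as dual edges, keeping
interaction and embedding distinct.

Placing each dual dart at the centroid of its face makes the dual itself a
geometrically coherent `cmap2`, so the same validator applies to both
representations.

## Building plots

`build_plot()` assembles a closed map from a declarative `plot_spec()`:
one `face_from_polygon()` per area (each a counterclockwise interior cycle
plus a clockwise provisional complement, sewn pairwise), `merge_maps()`
across coincident borders, recursive `embed_hole()` for children, and
`make_border_explicit()` to promote the single surviving complement to the
outside face. The pipeline is fully deterministic — areas in spec order,
dart ids by creation — so the same spec always serializes byte-identically.

Orientation convention: interior faces are counterclockwise (interior on
the left of every dart, positive signed area), the outside face and hole
cycles clockwise. This makes the "next dart with the smallest angle" rule
concrete and testable through signed areas.

Adjacent areas must share **whole edges** (a conforming tiling);
T-junctions are rejected rather than auto-split. The synthetic generator
only emits conforming specs, and `read_geojson()` inputs must satisfy the
same constraint. This is a real restriction for arbitrary GIS inputs, where
neighbouring parcels often share partial edges; splitting edges at foreign
vertices would be the natural extension.

## The synthetic generator

`generate_plot()` emulates the archetypal temperate alley-cropping system:
parallel understory vegetation strips carrying tree lines, separated by
crop alleys, wrapped by the outside face. Defaults are 2 lines of 3 trees
(0.5 m-margin 1 m tree squares on 2 m strips), one 12 m alley, 24 m plot
length, no jitter — a plot a French silvoarable trial would recognize:
strips of a couple of metres, alleys sized for machinery passes, trees
every 8 m. `jitter` perturbs tree centres uniformly (clamped so containment
and conformity always hold), emulating irregular plantings; the seed makes
every draw reproducible.

What the generator does *not* emulate: curved or non-rectilinear parcel
boundaries, partial-edge adjacency, overlapping canopies at generation
time, multi-level hierarchies deeper than strip→tree. Passing tests on
generated plots therefore demonstrate correctness of the topology engine on
conforming rectilinear plots, not robustness to arbitrary survey data.

## Dynamics

Attribute evolution (`set_attributes()`) touches only property tables; a
structural hash asserts the beta tables are untouched. Structural edits are
local surgery with a stability contract: *darts outside the affected faces
keep their ids*, so external references (simulation state attached to
darts, stored interface lists) survive edits elsewhere in the plot.

`grow_crown()` distinguishes two regimes. While the new crown stays inside
its strip, the edit is a resize of the embedded face: no top-level change.
Once the crown projection crosses a border, the affected ground faces are
re-tessellated: the tree contributes one sub-face per ground face it covers
(sharing a `group` attribute — the original tree's face id — because no
canonical answer exists to whether a grown tree is one face or several; two
tagged faces keep both readings available), the invaded crop region becomes
a `mixed` face carrying both tree and crop provenance, and the remainders
keep their face ids. New dual adjacencies (canopy–crop) appear; none are
lost — growth is monotone in adjacency. Crowns are axis-aligned rectangles
and each affected face must be invaded across a single straight border run;
other overlays raise "non-conforming overlay". General polygon crowns would
need a full overlay arrangement, deliberately out of scope.

`remove_element()` deletes an embedded face with its hole (thinning,
death), restoring the parent exactly: remove-then-re-add yields a map
attributed-isomorphic to the original, checked with a canonical form
(breadth-first dart relabelling per component from the lexicographically
smallest (element type, x, y) anchor). Top-level faces are merged into a
named neighbour by deleting the shared-edge pairs and reconnecting the
border cycles.

## Pattern matching

A `pattern()` is a small closed fragment plus roles and predicates. The
matched domain is the boundary darts of the *role-bearing* faces; the
fragment's own outside border is a closure artifact, not a constraint —
otherwise a line–crop–line pattern could never match inside a wider plot,
because the pattern's outside cycle is shorter than the target's. The dart
mapping must be injective, preserve `beta1` everywhere in the domain
(which pins each pattern face to a target face with an equal border
length) and preserve `beta2` between role faces. Matches are deduplicated
by the sorted set of matched target face ids, so the two symmetric
embeddings of a symmetric pattern count once: a 2-line plot contains the
line–crop–line service once, a (k+1)-line plot k times. Predicates cover
attribute equality, adjacency, betweenness ("crop must lay between two
tree lines": adjacent to both, which share no edge) and metrics, including
"width is a multiple of q" with a relative tolerance of 0.01·q — the
machine-width constraint.

The search anchors at a dart of the rarest element type (least branching)
and propagates in lockstep; correctness is anchor-independent, which the
tests assert by re-running from every anchor, and on targets of up to 24
darts the results are checked against brute-force enumeration.

## Numerical choices

* Coordinate tolerance 1e-9 m for node identity and geometric coherence
  (configurable per map). Plot geometry is metre-scale, so this is far
  below any physical feature but above double-precision noise.
* Signed areas via the shoelace formula; point-in-polygon through
  `pracma::inpolygon` with exact on-boundary exclusion for the *strict*
  containment demanded of embedded elements.
* Areas reported by `eval_metric()` subtract hole areas; centroids are
  area-weighted over the boundary cycle.
* Serialization: canonical JSON (schema `agromap-map/1`), darts and faces
  ordered by id, property keys sorted — byte-stable, human-diffable.
  `parse_map()` re-validates and refuses inconsistent beta tables.
* Determinism everywhere: no randomness outside the generator's seeded
  jitter.

## Problem sizes

The test suite builds its fixtures in code: kernel examples with 6–14
darts, archetypal plots with ~70 darts, property suites over 200 generated
plots (2–4 lines, 0–3 trees per line, jittered and regular), 25 randomized
edit sequences, and brute-force matching cross-checks on targets of at
most 24 top-level darts — sizes chosen so the whole suite runs in well
under a minute while still exercising every code path at the scale the
archetypal systems have.

## Known limitations

* Conforming tilings only; no automatic repair or edge splitting.
* Crowns and generated elements are axis-aligned rectangles; repeated
  growth events colliding with an earlier notch are rejected rather than
  re-tessellated.
* Matching runs at the top hierarchy level; patterns with explicit holes
  are not supported.
* Georeferencing is metadata: coordinates are treated as plot-local metres
  after subtracting the first point (identity affine); no projection
  support.
* 2D only; no volumes, no non-orientable surfaces, and no operator chains
  beyond `beta1`/`beta2`.
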