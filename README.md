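# agromap — combinatorial plot maps for agroforestry systems

Agroforestry plots (alley cropping, tree lines on understory vegetation
strips, scattered trees) are spatial systems whose functioning is driven by
the *adjacencies* between their elements: shade and root competition act
across the strip–crop border, pest regulation needs a crop alley flanked by
two tree lines, and every element exchanges with the world outside the
plot. Most plot models keep either the geometry (GIS coordinates) or the
topology (a graph), but not both, and struggle to keep the two consistent
while the system grows and is managed over decades.

agromap is an R library for people who model, design or analyse such
systems. It represents a plot as a **2D combinatorial map**: a set of
oriented half-edges (*darts*) with two operators,

* **β1** (permutation) — the next dart along the border of the same face,
* **β2** (involution) — the oppositely oriented partner across the shared
  edge, with β2(β2(d)) = d,

so that plot elements are faces (closed β1 cycles), interfaces are β2 edge
pairs, hierarchy is a *hole* (a tree face embedded in its strip's hole),
and the world outside the plot is an explicit `outside` face that makes β2
total. Nodes need not be stored — a node is an orbit of the operators —
and the structural health of a plot reduces to checkable axioms
(β1 bijective, β2 a fixed-point-free involution, geometric coherence, and
Euler's V − E + F = 2 per connected level).

The **dual map** — faces become nodes, darts become oriented relations,
with successor β1∘β2 — is derived on demand and is the natural carrier for
interaction and exchange models; it is always exactly consistent with the
structure. On top of the kernel the package provides an incremental plot
builder from polygons, dynamic edits (crown growth that subdivides the
invaded crop into mixed zones, planting, thinning) with guaranteed map
consistency, exact attributed pattern matching with metric constraints, a
synthetic alley-cropping generator, canonical JSON / GeoJSON / DOT
input-output, and a command-line interface.

## A worked example

```r
library(agromap)

# the archetypal system: 2 tree lines of 3 trees on understory strips,
# one 12 m crop alley between them, 24 m long
spec <- generate_plot(synth_params(n_lines = 2, trees_per_line = 3))
m <- build_plot(spec)
m
#> <cmap2: 68 darts, 10 faces, closed>

validate_map(m)
#> map is valid and closed

map_counts(m, level_darts(m))   # top level: 2 strips + 1 alley + outside
#>     V     E     F euler
#>     8    10     4     2

# the pest-regulation structure "crop between two tree lines" occurs once
count_matches(m, line_crop_line_pattern())
#> [1] 1

eval_metric(m, face_by_area(m, "alley1"), "height")   # alley width in metres
#> [1] 12

# ten years later: one tree's crown projects across the strip-crop border
t1 <- face_by_area(m, "tree1_1")
tb <- poly_bbox(face_polygon(m, t1))
grow_crown(m, t1, c(tb["xmin"] - 0.2, tb["xmax"] + 0.2, tb["ymin"], 4.5),
           label = "year 10")
sapply(attr(m, "new_faces"), function(f) face_element_type(m, f))
#> [1] "tree"  "mixed"

# the canopy-over-crop face is adjacent to the alley: a tree-crop
# interaction now exists in the dual map
faces_adjacent(m, attr(m, "new_faces")[2], face_by_area(m, "alley1"))
#> [1] TRUE
```

The 8 top-level nodes are the plot's 4 corners plus the 4 junctions where
strip–alley borders meet the plot boundary; the 10 edges are the β2 pairs
between the 4 top-level faces. After the growth event the tree is split in
two tagged faces — its part on the strip and a `mixed` face (crown over
crop) carrying both tree and crop provenance — total interior area is
conserved, every previously existing interface still exists, and the map
still validates closed.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "agromap.R", package = "agromap"))')
Rscript $CLI synth --n-lines 2 --trees-per-line 3 --out plot.geojson
Rscript $CLI build --in plot.geojson --out plot.json
Rscript $CLI validate --in plot.json      # exit 0 valid, 1 invalid
Rscript $CLI dual     --in plot.json --out dual.json
Rscript $CLI export   --in plot.json --out dual.dot --dual --collapse
```

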