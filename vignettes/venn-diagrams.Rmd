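---
title: "How vennkit computes and draws Venn diagrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How vennkit computes and draws Venn diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vennkit)
```

## The model

A Venn diagram of $n$ sets shows all $2^n - 1$ possible intersection
regions, whether or not they contain items. vennkit treats the diagram as
two parallel decompositions joined by a shared key:

* **Set algebra.** Every item of the union belongs to exactly one region,
  identified by its *region mask* — the length-$n$ binary inclusion vector
  (bit $i$ = membership of the $i$-th input set). The region for mask $m$
  contains $\bigcap_{i: m_i = 1} S_i \setminus \bigcup_{i: m_i = 0} S_i$.
  Counts and percentages (of the union) are per-region statistics.
* **Geometry.** Each set is a closed polygonal shape; the plane decomposes
  into the same $2^n - 1$ regions by the same formula, with polygon
  intersection/union/difference in place of the item-set operations.

The mask is the single join ID: `build_plot_data()` matches the region
polygons to the region member lists by mask, never by position or name, and
region names (`"A/B"`) are derived from the mask at join time. Everything
downstream — querying, tables, rendering — runs on this joined object.

Regions are ordered by ascending number of included sets, ties broken by
the tuple of included set indices, so `"10", "01", "11"` for two sets. This
keeps tables and legends stable, with single-set regions first.

Items are opaque strings, compared case-sensitively after stripping
surrounding whitespace; duplicates within a set are removed on ingest and
the removal is logged. Percentages round half away from zero to one
decimal; with an empty union all percentages are 0. One consequence worth
stating: percentages are fractions of the union of the input sets, not of
some larger universe — with list input there are no "outside" items.

## Polygon boolean operations

No fixed layout can serve custom shapes, so the geometric side rests on
general polygon boolean operations, implemented in the package and exposed
as `poly_intersect()`, `poly_union()`, `poly_difference()` — deliberately
the same algebra as the item-level operations.

The engine is a segment classifier. Both boundaries are split at every
mutual crossing; each sub-segment is classified as inside or outside the
other shape by the winding number of its midpoint, or as coincident with a
partner sub-segment; a rule table per operation selects the surviving
directed sub-segments; survivors are stitched into closed rings by taking
the sharpest left turn at junctions, which yields simple rings with the
interior on the left (outer rings counter-clockwise, holes clockwise, so a
shape's area is its summed signed ring area).

Numerical choices:

* All coordinates snap to a $2^{-30}$ grid (about $10^{-9}$ plot units) on
  ingest and at computed intersection points. Genuinely coincident geometry
  — a repeated shape, two rectangles sharing a frame edge — therefore
  compares *exactly equal*, and the degenerate cases ($a \setminus a$,
  unions of adjacent shapes, identical circles) resolve through the
  coincidence rules rather than through epsilon comparisons.
* Collinear overlaps split each segment at the other's endpoints, so
  coincident portions become identical sub-segments.
* Output rings with area below $10^{-9}$ square units are slivers and are
  dropped; a region can legitimately be empty.
* Smooth curves discretize at 720 vertices per full turn. At that
  resolution the two-circle lens area agrees with the closed form
  $2r^2\cos^{-1}\!\frac{d}{2r} - \frac{d}{2}\sqrt{4r^2 - d^2}$ to relative
  error below $10^{-3}$, which is far below anything visible in a figure.
* There is no randomness anywhere in the geometry: identical inputs give
  identical coordinates, which is what makes SVG output byte-deterministic.

Self-intersecting input rings are rejected with the offending ring named;
shapes produced by the package's own constructors and operations are known
clean and skip the check.

`compute_regions()` does not evaluate the $2^n - 1$ mask formulas
independently. It decomposes incrementally: each shape in turn splits every
existing cell into its inside and outside parts (and contributes the part
of itself outside everything seen so far). That costs about $2^{n+1}$
boolean operations instead of $n 2^n$, and the later operations run on
small cell polygons. `validate_layout()` then measures, not assumes, the
Venn property: it counts positive-area regions (expected $2^n - 1$),
computes the maximum pairwise region overlap by actual polygon
intersection, and compares summed region areas against the union area, all
with tolerance $\varepsilon = 10^{-6} \times$ union area.

## Built-in layouts

Coordinates live in a nominal $[0,1]^2$ frame, $y$ up.

**Classic family** (n = 2–4): two circles (radius 0.27, centers 0.30
apart), the standard three-circle rosette, and four congruent ellipses
(semi-axes 0.32 and 0.16, rotations $\pm 45^\circ$, mirrored center
offsets). The ellipse parameters were tuned once until `validate_layout()`
passed and are frozen as package constants; validity is defined by the
validation report, not by coordinate equality with any other software.

**Constructive family** (n = 3–7), an Edwards-style construction:

* set 1: left half-slab of the frame; set 2: lower half-slab;
* set 3: a disc of radius $r_0 = 0.28$ at the center;
* set $k \ge 4$: a cogwheel (gear) disc whose boundary radius alternates
  between $r_0 - w_k$ and $r_0 + w_k$ with $2^{k-3}$ teeth
  ($w_4..w_7 = 0.10, 0.065, 0.042, 0.020$).

Each tooth arc starts at half a tooth-width ($\pi / 2t$ for $t$ teeth), so
the tooth states of gears 4..7 over the angular cells of one quadrant run
through a reflected Gray code: every combination of tooth/valley states
occurs inside every quadrant. Combined with the nested radial widths, every
mask over the disc and gears is realized in every quadrant, which is what
makes all $2^n - 1$ regions non-empty — and `validate_layout()` confirms it
numerically for every $n$ rather than trusting the argument.

Edwards' description speaks of *bands* around the circle. A band is an
annulus with two boundary curves; vennkit uses gear *discs* (star-shaped
interiors of a single closed curve) instead, so that every set keeps one
closed boundary polyline, as the data model and the classical
Jordan-curve convention expect. The resulting region structure is
equivalent — validity is checked, not inherited.

**Novel-shape layouts.** `layout_rounded_rectangles()` realizes the
four-set arrangement with congruent rounded rectangles instead of ellipses
(same frozen centers and rotations). `layout_six_triangles()` composes a
complete 6-set Venn diagram from exactly six triangles, read from a
packaged coordinate fixture (`inst/extdata/six_triangles.csv`). Those
coordinates were found by a computer search: triangles were added one at a
time, each new triangle optimized (Nelder–Mead over its six vertex
coordinates from many random starts) to split every existing region into
two non-trivial parts, with a joint simulated-annealing pass over all
vertices whenever a stage stalled; the first configuration for which
`validate_layout()` reported 63 positive, disjoint, tiling regions was
frozen. The fixture is synthetic in that sense — its justification is the
validation report, which the test suite recomputes on every run.

## Label placement

Region labels need a point genuinely inside the region, and Venn regions
are routinely crescents whose centroid lies outside them.
`region_label_anchor()` approximates the *pole of inaccessibility* — the
interior point farthest from the boundary — of the region's largest part,
by a deterministic coarse-to-fine grid search (24×24 over the bounding box,
then two 12×12 refinements around the best cell). For multi-part regions
the largest part (outer ring net of its holes) carries the label;
zero-area regions get no geometric label, though their counts stay in the
region table. Set labels sit outside the diagram: offset outward from the
shape's boundary point farthest from the layout centroid, overridable by
user-supplied anchor coordinates.

## Rendering

Figures draw in four independent layers, bottom to top: (1) region
polygons filled by a gradient mapped to count or percent, with a color-bar
legend; (2) set edges; (3) set labels; (4) region labels. `layer_toggle()`
switches layers individually; `fill_by = "none"` gives a flat fill with no
legend.

The default colormap is viridis — continuous, perceptually uniform, dark
blue to yellow — so equal count differences read as comparable color
differences and the map survives grayscale conversion. Fill position is
linear between the minimum and maximum region value (the legend spans
exactly that range); zero-count regions are filled at the colormap minimum
rather than left blank, so the partition stays visible. Text sizes are
figure-relative with a floor of 0.5 cex; labels never auto-hide on
overlap — for seven sets some crowding is the honest picture, and an UpSet
plot is the better tool past that point.

SVG is written by the package itself with fixed number formatting and no
timestamps, so identical input produces byte-identical files; element ids
(`region-<mask>`, `edge-<name>`, `setlabel-<name>`, `regionlabel-<mask>`)
make figures scriptable and testable. PNG and PDF go through the standard
R devices and inherit their metadata, so only SVG carries the
byte-determinism guarantee.

## The synthetic-data generator

`fixture_spec()` / `generate_fixture()` construct collections with exactly
prescribed per-region counts: for each mask, fresh items named
`<prefix><mask>_<i>` are added to exactly the flagged sets. This makes the
expected output of the entire pipeline known by construction — the
end-to-end test is that `to_region_table()` reproduces the prescription
exactly, for 100 multinomially drawn prescriptions per $n$ (60 items each,
`random_spec()` seeded).

What the generator emulates is the combinatorial structure of overlapping
identifier lists; what it does not emulate is anything about real
identifiers — vocabulary, capitalization quirks, whitespace damage,
near-duplicates. Passing tests therefore certify the region arithmetic and
the join, not robustness to dirty input files (the readers' trimming and
de-duplication are tested separately, on small hand-written cases).

## Degenerate inputs and edge cases

* Empty sets are legal; their regions get count 0 and percentages stay
  defined (0 when the union is empty).
* Identical sets are legal; all exclusive regions are empty.
* One set or more than seven sets is rejected at construction, with the
  error for many sets pointing to UpSet plots.
* Geometrically empty regions (possible with custom layouts) are kept in
  all tables with an empty-geometry flag; an *invalid* custom layout
  renders anyway — the validation report travels in the plot-data metadata
  as a warning, and the CLI prints it — because a half-finished custom
  shape you can see is more useful than an error.

## Problem sizes and runtime

The package validates all builtin layouts (classic 2–4, constructive 3–7)
by full region computation; the seven-set validation is the most expensive
single step at roughly ten seconds of polygon arithmetic. The test suite
uses 100 fixtures per $n$ at 60 items each for the membership oracle and
720-vertex discretization everywhere; these sizes exercise every code path
at comfortable margins while keeping a full run in minutes.

## Known limitations

* Layouts are fixed, not area-proportional: region area carries no
  quantitative meaning (that is an Euler diagram, out of scope; the fill
  gradient is the quantitative channel here).
* All curves are polygonal approximations; exported arcs are 720-gon arcs,
  not true curve elements.
* The boolean engine targets the coordinate scales of plot layouts
  (unit-order magnitudes, $2^{-30}$ snapping); it is not a general-purpose
  computational-geometry library for extreme aspect ratios or microscopic
  features.
* Six- and seven-set diagrams are complete but dense; past seven sets the
  package refuses and recommends an UpSet plot.
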