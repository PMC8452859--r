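# vennkit

Venn diagrams for 2–7 sets, with the region data as first-class output.

Comparing identifier lists — differentially expressed genes across
contrasts, OTUs across sites, compounds across assays — raises two
questions at once: *which* items fall in each overlap, and how to *show*
the overlaps. vennkit answers both from one object. It decomposes 2–7
named sets into all 2^n − 1 regions twice — once over the items
(membership, counts, percentages of the union) and once over the plane
(polygon regions of a layout) — and joins the two through region masks,
binary inclusion vectors like `"110"` that uniquely identify each region.
From the joined object you get a queryable table of every region's members
and a publication-quality figure with count-mapped region filling.

The geometric side is self-contained: polygon boolean operations
(intersection, union, difference — the same algebra as the item-level set
operations), classic circle/ellipse layouts, an Edwards-style cogwheel
construction that scales to seven sets, layouts composed from your own
shapes (triangles, rounded rectangles, arbitrary polygons from a CSV), and
a layout validator that checks a shape arrangement really produces all
2^n − 1 disjoint regions.

## A worked example

```r
library(vennkit)

gene_sets <- list(
  heat    = c("HSPA1A", "HSPA1B", "DNAJB1", "BAG3", "HSPB1", "FOS"),
  cold    = c("CIRBP", "RBM3", "FOS", "JUN", "HSPB1"),
  osmotic = c("NFAT5", "AKR1B1", "HSPB1", "FOS", "SLC6A12")
)

v  <- make_venn(gene_sets)
pd <- build_plot_data(v, builtin_layout(3))
to_region_table(pd)
```

```
# A tibble: 7 × 5
  mask  name              count percent members
  <chr> <chr>             <int> <chr>   <chr>
1 100   heat                  4 33.3%   "HSPA1A;HSPA1B;DNAJB1;BAG3"
2 010   cold                  3 25.0%   "CIRBP;RBM3;JUN"
3 001   osmotic               3 25.0%   "NFAT5;AKR1B1;SLC6A12"
4 110   heat/cold             0 0.0%    ""
5 101   heat/osmotic          0 0.0%    ""
6 011   cold/osmotic          0 0.0%    ""
7 111   heat/cold/osmotic     2 16.7%   "HSPB1;FOS"
```

Each row is one of the 2^3 − 1 = 7 regions: the mask `"111"` region holds
the two genes induced by all three stresses (`HSPB1`, `FOS` — 16.7% of the
12-gene union), and every gene appears in exactly one row, so the counts
sum to the union size. The same information is queryable directly:
`get_region_items(pd, "111")` (or by name, `"heat/cold/osmotic"`) returns
`HSPB1 FOS`.

Render and export:

```r
fig <- render(pd, venn_style(fill_by = "count"))
export(fig, "stress_venn.svg")          # deterministic SVG
export(fig, "stress_venn.png", dpi = 300)
```

The figure has four layers — gradient-filled regions with a color-bar
legend, set edges, set labels, region labels — individually switchable:

```r
render(pd, layer_toggle(venn_style(), 4, FALSE))   # no region labels
```

Beyond the classic layouts: `builtin_layout(7)` gives a complete seven-set
diagram (Edwards-style cogwheels), `layout_six_triangles()` a six-set
diagram made of exactly six triangles, and `read_shape_csv()` brings your
own shapes; `validate_layout()` reports whether any arrangement truly
yields all 2^n − 1 disjoint regions.

## Command line

```sh
Rscript inst/cli/vennkit-plot    --sets heat.txt,cold.txt,osmotic.txt --out venn.svg
Rscript inst/cli/vennkit-regions --sets heat.txt,cold.txt,osmotic.txt --out regions.tsv
```

One item per line per file; `--tsv` (set_name, item) and `--json` inputs,
`--layout edwards|classic|custom:<shapes.csv>`, `--fill-by percent`, and a
YAML `--config` are available; defaults need nothing beyond the inputs and
`--out`.

## Scope

vennkit draws Venn diagrams: every region is shown regardless of emptiness
and region areas are not proportional to counts (that is an Euler diagram,
deliberately out of scope — the fill gradient is the quantitative
channel). Above seven sets it refuses and suggests an UpSet plot. Inputs
are identifier lists; extracting identifiers from FASTA/VCF/GFF is the
caller's job.
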