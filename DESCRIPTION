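Package: vennkit
Title: Venn Diagrams for Two to Seven Sets with Queryable Region Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computes both the set-algebraic and the geometric decomposition
    of 2-7 overlapping sets into the 2^n - 1 regions of a Venn diagram,
    joins them through region masks into a layered plot-data object,
    renders publication-quality diagrams with count-mapped region filling,
    and exposes region membership as queryable, exportable tables.
    Includes classic circle/ellipse layouts, a constructive Edwards-style
    layout family for up to seven sets, polygon boolean operations for
    user-defined shapes, and deterministic SVG as well as PNG/PDF export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    tibble,
    tools,
    utils,
    viridisLite,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
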