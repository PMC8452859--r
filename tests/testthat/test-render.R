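# Rendering: four layers, gradient fill mapping, deterministic SVG export.

svg_census <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  list(
    regions = length(xml2::xml_find_all(doc, "//d1:path[starts-with(@id, 'region-')]", ns)),
    edges = length(xml2::xml_find_all(doc, "//d1:path[starts-with(@id, 'edge-')]", ns)),
    set_labels = length(xml2::xml_find_all(doc, "//d1:text[starts-with(@id, 'setlabel-')]", ns)),
    region_labels = length(xml2::xml_find_all(doc, "//d1:text[starts-with(@id, 'regionlabel-')]", ns)),
    legend = length(xml2::xml_find_all(doc, "//d1:g[@id='legend']", ns))
  )
}

four_set_fig <- function() {
  v <- generate_fixture(random_spec(4, 80, seed = 11),
                        set_names = c("A", "B", "C", "D"))
  render(build_plot_data(v, builtin_layout(4)), venn_style())
}

test_that("the default figure carries all four layers in the SVG", {
  skip_if_not_installed("xml2")
  path <- withr::local_tempfile(fileext = ".svg")
  export(four_set_fig(), path)
  cs <- svg_census(path)
  expect_identical(cs$regions, 15L)
  expect_identical(cs$edges, 4L)
  expect_identical(cs$set_labels, 4L)
  expect_lte(cs$region_labels, 15L)
  expect_gt(cs$region_labels, 0L)
  expect_identical(cs$legend, 1L)
})

test_that("SVG export is byte-deterministic", {
  fig <- four_set_fig()
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  export(fig, p1)
  export(fig, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("layer toggles suppress exactly their layer", {
  skip_if_not_installed("xml2")
  st <- venn_style()
  edges_only <- layer_toggle(layer_toggle(layer_toggle(st, 1, FALSE), 3, FALSE),
                             4, FALSE)
  fig <- four_set_fig()
  fig$style <- edges_only
  path <- withr::local_tempfile(fileext = ".svg")
  export(fig, path)
  cs <- svg_census(path)
  expect_identical(cs$regions, 0L)
  expect_identical(cs$edges, 4L)
  expect_identical(cs$set_labels, 0L)
  expect_identical(cs$region_labels, 0L)
  # toggling twice restores the original
  expect_identical(layer_toggle(layer_toggle(st, 2, FALSE), 2, TRUE), st)
  expect_error(layer_toggle(st, 5, TRUE), "layer")
})

test_that("fill positions are monotone in count and legend spans the range", {
  v <- generate_fixture(fixture_spec(2, c("10" = 8, "01" = 2, "11" = 5)),
                        set_names = c("A", "B"))
  fig <- render(build_plot_data(v, builtin_layout(2)))
  sc <- build_scene(fig)
  fills <- stats::setNames(sc$region_fills, sc$regions$mask)
  ramp <- colormap_ramp("viridis")
  pos_of <- function(col) which(ramp(seq(0, 1, length.out = 256)) == col)[1]
  expect_lt(pos_of(fills[["01"]]), pos_of(fills[["11"]]))
  expect_lt(pos_of(fills[["11"]]), pos_of(fills[["10"]]))
  expect_identical(sc$legend_range, c(2L, 8L))
  # equal counts map to identical colors
  v2 <- generate_fixture(fixture_spec(2, c("10" = 3, "01" = 3, "11" = 1)),
                         set_names = c("A", "B"))
  sc2 <- build_scene(render(build_plot_data(v2, builtin_layout(2))))
  f2 <- stats::setNames(sc2$region_fills, sc2$regions$mask)
  expect_identical(f2[["10"]], f2[["01"]])
})

test_that("fill_by = none flattens fills and drops the legend", {
  skip_if_not_installed("xml2")
  fig <- four_set_fig()
  fig$style <- venn_style(fill_by = "none")
  sc <- build_scene(fig)
  expect_length(unique(sc$region_fills), 1L)
  expect_null(sc$legend_range)
  path <- withr::local_tempfile(fileext = ".svg")
  export(fig, path)
  expect_identical(svg_census(path)$legend, 0L)
})

test_that("region labels sit inside their region polygon", {
  pd <- four_set_fig()$pd
  for (i in seq_len(nrow(pd$regions))) {
    p <- pd$regions$poly[[i]]
    a <- pd$regions$label_anchor[[i]]
    if (poly_is_empty(p)) {
      expect_null(a)
    } else {
      expect_true(point_in_poly(rbind(a), p))
    }
  }
})

test_that("PNG export honours the requested pixel dimensions", {
  skip_if_not_installed("png")
  fig <- render(build_plot_data(example_venn2(), builtin_layout(2)),
                venn_style(width = 4, height = 3))
  path <- withr::local_tempfile(fileext = ".png")
  export(fig, path, dpi = 150)
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], c(3L * 150L, 4L * 150L))
})

test_that("export rejects unknown formats and unwritable paths", {
  fig <- render(build_plot_data(example_venn2(), builtin_layout(2)))
  expect_error(export(fig, "x.bmp", format = "bmp"), "unknown format")
  expect_error(export(fig, "/no/such/dir/x.svg"), "directory does not exist")
})

test_that("styles validate their inputs", {
  expect_error(venn_style(fill_by = "area"), "arg")
  expect_error(style_from_config(list(colour = "red")), "unknown style option")
  st <- style_from_config(list(fill_by = "percent", legend = FALSE))
  expect_identical(st$fill_by, "percent")
  expect_false(st$legend)
  v <- example_venn2()
  pd <- build_plot_data(v, builtin_layout(2))
  expect_error(render(pd, venn_style(edge_color = c(Z = "red"))),
               "unknown set name")
  fig <- render(pd, venn_style(edge_color = c(A = "red", B = "blue")))
  expect_s3_class(fig, "venn_figure")
})
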