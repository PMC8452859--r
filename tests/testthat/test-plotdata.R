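# The mask-joined plot-data object, querying and table export.

test_that("build_plot_data joins geometry and membership by mask", {
  v <- example_venn2()
  pd <- build_plot_data(v, builtin_layout(2))
  expect_s3_class(pd, "venn_plot_data")
  r11 <- pd$regions[pd$regions$mask == "11", ]
  expect_identical(r11$count, 2L)
  expect_setequal(r11$members[[1]], c("b", "c"))
  expect_gt(r11$area, 0)
  # the lens region of two overlapping equal circles is the smallest region
  expect_identical(pd$regions$mask[which.min(pd$regions$area)], "11")
  expect_identical(pd$union_size, 4L)
  expect_identical(pd$set_edges$set_size, c(3L, 3L))
  # join completeness: masks equal those of both sides, each exactly once
  expect_identical(sort(pd$regions$mask), sort(region_masks(2)))
  expect_error(build_plot_data(v, builtin_layout(3)), "2 sets")
})

test_that("empty sets keep geometry but zero all counts", {
  v <- make_venn(list(A = character(0), B = character(0)), quiet = TRUE)
  pd <- suppressWarnings(build_plot_data(v, builtin_layout(2)))
  expect_true(all(pd$regions$count == 0L))
  expect_true(all(pd$regions$percent == 0))
  expect_true(all(pd$regions$area[!pd$regions$empty] > 0))
})

test_that("attach_sets completes a geometry-first workflow idempotently", {
  lay <- builtin_layout(2)
  pd0 <- plot_data_from_layout(lay, validate = FALSE)
  expect_true(anyNA(pd0$regions$count))
  v <- example_venn2()
  pd1 <- attach_sets(pd0, v)
  pd2 <- attach_sets(pd1, v)
  expect_identical(pd1$regions$count, pd2$regions$count)
  expect_identical(pd1$regions$members, pd2$regions$members)
  expect_identical(pd1$union_size, 4L)
  expect_error(attach_sets(pd1, make_venn(list(A = "a", B = "b", C = "c"),
                                          quiet = TRUE)), "3 sets")
})

test_that("invalid custom layouts carry a validation warning, not an error", {
  broken <- shape_layout(list(circle(c(0.2, 0.5), 0.1),
                              circle(c(0.8, 0.5), 0.1)))
  pd <- plot_data_from_layout(broken, validate = TRUE)
  pd <- attach_sets(pd, example_venn2())
  expect_false(is.null(pd$metadata$validation_warning))
  expect_match(pd$metadata$validation_warning, "2/3 positive regions")
  expect_s3_class(render(pd), "venn_figure")
})

test_that("get_region_items resolves masks and names, and rejects others", {
  pd <- build_plot_data(example_venn2(), builtin_layout(2))
  expect_setequal(get_region_items(pd, "11"), c("b", "c"))
  expect_identical(get_region_items(pd, "A/B"), get_region_items(pd, "11"))
  expect_error(get_region_items(pd, "0000"), "valid masks")
  expect_error(get_region_items(pd, "nope"), "valid names")
})

test_that("to_region_table matches the enumeration oracle", {
  v <- make_venn(list(A = "a", B = "b"), quiet = TRUE)
  tbl <- to_region_table(build_plot_data(v, builtin_layout(2)))
  expect_identical(tbl$mask, c("10", "01", "11"))
  expect_identical(tbl$name, c("A", "B", "A/B"))
  expect_identical(tbl$count, c(1L, 1L, 0L))
  expect_identical(tbl$percent, c("50.0%", "50.0%", "0.0%"))
  expect_identical(tbl$members, c("a", "b", ""))
})

test_that("region tables round-trip through TSV", {
  v <- generate_fixture(random_spec(3, 60, seed = 7))
  pd <- build_plot_data(v, builtin_layout(3))
  tbl <- to_region_table(pd)
  expect_identical(nrow(tbl), 7L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_region_table(tbl, path)
  back <- read_region_table(path)
  expect_identical(back$mask, tbl$mask)
  expect_identical(back$count, tbl$count)
  expect_identical(back$members, tbl$members)
})

test_that("prescribed counts survive the full pipeline for every n", {
  for (n in 2:7) {
    spec <- random_spec(n, 120, seed = 1000 + n)
    v <- generate_fixture(spec)
    pd <- build_plot_data(v, builtin_layout(n))
    tbl <- to_region_table(pd)
    expect_identical(stats::setNames(tbl$count, tbl$mask), spec$counts,
                     info = paste("n =", n))
  }
})

test_that("the six-triangle fixture pipeline yields 63 joined regions", {
  lay <- layout_six_triangles()
  spec <- random_spec(6, 300, seed = 36)
  v <- generate_fixture(spec)
  pd <- attach_sets(plot_data_from_layout(lay, validate = FALSE), v)
  expect_identical(nrow(pd$regions), 63L)
  tbl <- to_region_table(pd)
  expect_identical(stats::setNames(tbl$count, tbl$mask), spec$counts)
})
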