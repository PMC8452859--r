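# Item-level set model and region statistics.

test_that("make_venn enforces the 2..7 set range and clean names", {
  expect_s3_class(make_venn(list(A = c("a", "b"), B = c("b", "c"))), "venn")
  eight <- stats::setNames(rep(list("x"), 8), paste0("S", 1:8))
  expect_error(make_venn(eight), "UpSet")
  expect_error(make_venn(eight), "unsupported set count")
  expect_error(make_venn(list(A = "a")), "unsupported set count")
  expect_error(make_venn(list(A = "a", A = "b")), "duplicate set names")
  expect_error(make_venn(stats::setNames(list("a", "b"), c("A", ""))),
               "non-empty name")
})

test_that("make_venn deduplicates and trims items, reporting removals", {
  expect_message(v <- make_venn(list(A = c("a", "a", " b "), B = "c")),
                 "removed 1 duplicate")
  expect_setequal(v$sets$A, c("a", "b"))
  expect_identical(attr(v, "dedup"), c(A = 1L, B = 0L))
  # trimming happens before comparison, so "a" and " a" collide
  v2 <- make_venn(list(A = c("a", " a"), B = "b"), quiet = TRUE)
  expect_identical(v2$sets$A, "a")
})

test_that("region_members returns exactly-these-sets membership", {
  v <- example_venn2()
  expect_setequal(region_members(v, "11"), c("b", "c"))
  expect_identical(region_members(v, "10"), "a")
  expect_identical(region_members(v, "01"), "d")
  expect_error(region_members(v, "110"), "2 sets")
  expect_error(region_members(v, "00"), "all-zero")
})

test_that("identical and empty sets are handled", {
  v <- make_venn(list(A = "x", B = "x"), quiet = TRUE)
  expect_identical(region_members(v, "11"), "x")
  expect_length(region_members(v, "10"), 0)
  expect_length(region_members(v, "01"), 0)
  ve <- make_venn(list(A = character(0), B = character(0)), quiet = TRUE)
  for (m in region_masks(2)) expect_length(region_members(ve, m), 0)
  expect_true(all(all_regions(ve)$percent == 0))
})

test_that("all_regions enumerates 2^n - 1 regions with exact counts", {
  v3 <- make_venn(list(A = "a", B = "b", C = "c"), quiet = TRUE)
  expect_identical(nrow(all_regions(v3)), 7L)

  v <- make_venn(list(A = "a", B = "b"), quiet = TRUE)
  rg <- all_regions(v)
  expect_identical(rg$mask, c("10", "01", "11"))
  expect_identical(rg$count, c(1L, 1L, 0L))
  expect_identical(rg$percent, c(50, 50, 0))
  expect_identical(rg$name, c("A", "B", "A/B"))
})

test_that("all_regions agrees with the brute-force oracle at n = 7", {
  spec <- random_spec(7, 500, seed = 421)
  v <- generate_fixture(spec)
  rg <- all_regions(v)
  expect_identical(nrow(rg), 127L)
  expect_identical(sum(rg$count), union_size(v))
  oracle <- oracle_region_members(v)
  for (i in seq_len(nrow(rg))) {
    expect_setequal(rg$members[[i]], oracle[[rg$mask[i]]])
  }
})

test_that("set sizes equal region-count marginals", {
  v <- make_venn(list(A = c("a", "b", "c"), B = "b"), quiet = TRUE)
  expect_identical(set_sizes(v)$size, c(3L, 1L))
  spec <- random_spec(4, 200, seed = 99)
  vf <- generate_fixture(spec)
  rg <- all_regions(vf)
  sz <- set_sizes(vf)
  for (i in seq_len(vf$n)) {
    inc <- vapply(rg$mask, function(m) mask_bits(m)[i] == 1L, logical(1))
    expect_identical(sum(rg$count[inc]), sz$size[i])
  }
})

test_that("percentages format with one-decimal round-half-away", {
  expect_identical(format_percent(1, 4), "25.0%")
  expect_identical(format_percent(0, 10), "0.0%")
  expect_identical(format_percent(1, 3), "33.3%")
  expect_identical(format_percent(2, 3), "66.7%")
  # 0.125 of 100% -> 12.5%; half-away keeps the 5
  expect_identical(format_percent(1, 8), "12.5%")
  expect_identical(format_percent(0, 0), "0.0%")
  expect_error(format_percent(5, 4), "exceeds")
})

test_that("percent sums stay within rounding tolerance of 100", {
  for (n in 2:7) {
    v <- generate_fixture(random_spec(n, 173, seed = n))
    s <- sum(all_regions(v)$percent)
    k <- 2^n - 1
    expect_gte(s, 100 - 0.05 * k)
    expect_lte(s, 100 + 0.05 * k)
  }
})

test_that("canonical mask order is size-then-index-lexicographic", {
  expect_identical(region_masks(2), c("10", "01", "11"))
  expect_identical(region_masks(3),
                   c("100", "010", "001", "110", "101", "011", "111"))
  expect_length(region_masks(7), 127L)
  expect_error(region_masks(8), "unsupported set count")
})

test_that("mask helpers round-trip and validate", {
  expect_identical(mask_bits("101"), c(1L, 0L, 1L))
  expect_identical(mask_from_bits(c(1, 0, 1)), "101")
  expect_identical(mask_name("110", c("A", "B", "C")), "A/B")
  expect_identical(mask_name("110", c("A", "B", "C"), sep = " & "), "A & B")
  expect_error(check_mask("0x1"), "0s and 1s")
})
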