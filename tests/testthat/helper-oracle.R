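# Brute-force oracle: classify every item of the union directly by its
# membership bit vector, independently of the set-difference route used by
# region_members()/all_regions().
oracle_region_members <- function(venn) {
  items <- sort(unique(unlist(venn$sets)))
  masks <- region_masks(venn$n)
  out <- stats::setNames(rep(list(character(0)), length(masks)), masks)
  for (it in items) {
    bits <- vapply(venn$sets, function(s) it %in% s, logical(1))
    m <- paste(as.integer(bits), collapse = "")
    out[[m]] <- c(out[[m]], it)
  }
  out
}

# a small, fixed collection reused across tests
example_venn2 <- function() {
  make_venn(list(A = c("a", "b", "c"), B = c("b", "c", "d")), quiet = TRUE)
}

# layout validation is the expensive computation in the suite; run each
# builtin layout once per session and share the report
.layout_cache <- new.env(parent = emptyenv())

cached_report <- function(n, family) {
  key <- paste0(family, n)
  if (is.null(.layout_cache[[key]])) {
    .layout_cache[[key]] <- validate_layout(builtin_layout(n, family))
  }
  .layout_cache[[key]]
}

cached_six_triangle_report <- function() {
  if (is.null(.layout_cache[["tri6"]])) {
    .layout_cache[["tri6"]] <- validate_layout(layout_six_triangles())
  }
  .layout_cache[["tri6"]]
}
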