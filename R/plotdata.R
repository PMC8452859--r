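# The layered plot-data object: region geometry and region membership joined
# through region masks, plus per-set edge/label/size data. This is the
# queryable object every downstream step (rendering, tables, export) runs on.

#' Join a Venn collection with a layout into plot data
#'
#' Regions carry both geometry (from [compute_regions()]) and membership
#' (from [all_regions()]), matched by region mask; set edges carry boundary
#' polylines, label anchors and set sizes. The mask is the single source of
#' truth: region names are derived from it at join time.
#'
#' @param venn A `venn` collection.
#' @param layout A `shape_layout` with `layout$n == venn$n`.
#' @param sep Separator for region names.
#' @param validate If `TRUE`, run [validate_layout()] and store the report
#'   in the result's metadata (a warning is kept, not raised, so exploratory
#'   shapes still render).
#' @return An object of class `venn_plot_data`: fields `n`, `set_edges`
#'   (tibble: `set_index`, `name`, `edge`, `label_anchor`, `set_size`),
#'   `regions` (tibble: `mask`, `name`, `poly`, `area`, `label_anchor`,
#'   `members`, `count`, `percent`), `union_size`, `metadata`.
#' @export
#' @examples
#' v <- make_venn(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' pd <- build_plot_data(v, builtin_layout(2))
#' pd$regions[, c("mask", "name", "count", "percent")]
build_plot_data <- function(venn, layout, sep = "/", validate = FALSE) {
  check_venn(venn)
  check_layout(layout)
  if (venn$n != layout$n) {
    stop("collection has ", venn$n, " sets but the layout has ", layout$n,
         call. = FALSE)
  }
  pd <- plot_data_from_layout(layout, set_names = names(venn$sets),
                              validate = validate)
  attach_sets(pd, venn, sep = sep, validate = FALSE)
}

#' Geometry-only plot data from a layout
#'
#' The custom-shape workflow: build the geometric half of the plot data
#' first (regions, anchors, edges), then attach item sets later with
#' [attach_sets()].
#'
#' @param layout A `shape_layout`.
#' @param set_names Optional set names (defaults to `Set1..Setn`).
#' @param validate If `TRUE`, attach a [validate_layout()] report as
#'   metadata; an invalid layout yields a validation warning in the
#'   metadata, not an error.
#' @return A `venn_plot_data` whose membership columns are empty.
#' @export
plot_data_from_layout <- function(layout, set_names = NULL, validate = TRUE) {
  check_layout(layout)
  n <- layout$n
  if (is.null(set_names)) set_names <- paste0("Set", seq_len(n))
  if (length(set_names) != n) stop("need one set name per shape", call. = FALSE)
  regions <- compute_regions(layout)
  anchors <- lapply(regions$poly, function(p) {
    if (poly_is_empty(p) || poly_area(p) <= 0) NULL else region_label_anchor(p)
  })
  set_edges <- tibble::tibble(
    set_index = seq_len(n),
    name = set_names,
    edge = layout$edges,
    label_anchor = lapply(seq_len(n), function(i) label_position(layout, i)),
    set_size = NA_integer_
  )
  rg <- tibble::tibble(
    mask = regions$mask,
    name = NA_character_,
    poly = regions$poly,
    area = regions$area,
    empty = regions$empty,
    label_anchor = anchors,
    members = vector("list", nrow(regions)),
    count = NA_integer_,
    percent = NA_real_
  )
  metadata <- list()
  if (validate) {
    rep <- validate_layout(layout, regions = regions)
    metadata$validation <- rep
    if (!rep$valid) {
      metadata$validation_warning <- sprintf(
        "layout is not a complete %d-set Venn diagram: %d/%d positive regions, max overlap %.3g, area discrepancy %.3g",
        n, rep$positive_regions, rep$expected_regions,
        rep$max_pairwise_overlap, rep$area_discrepancy)
    }
  }
  structure(list(n = n, set_edges = set_edges, regions = rg,
                 union_size = NA_integer_, metadata = metadata),
            class = "venn_plot_data")
}

#' Attach item sets to geometry-only plot data
#'
#' Fills (or overwrites — attaching twice is idempotent) the membership side
#' of a `venn_plot_data`: region members, counts, percentages, set names and
#' set sizes. Enables the custom-shape workflow: shape first, values later.
#'
#' @param pd A `venn_plot_data` (with or without values).
#' @param venn A `venn` collection with `venn$n == pd$n`.
#' @param sep Separator for region names.
#' @param validate If `TRUE` and the plot data carries no validation report
#'   yet, nothing is recomputed; validation happens at layout ingest.
#' @return The completed `venn_plot_data`.
#' @export
attach_sets <- function(pd, venn, sep = "/", validate = FALSE) {
  check_plot_data(pd)
  check_venn(venn)
  if (venn$n != pd$n) {
    stop("collection has ", venn$n, " sets but the plot data has ", pd$n,
         call. = FALSE)
  }
  vals <- all_regions(venn, sep = sep)
  ord <- match(pd$regions$mask, vals$mask)
  if (anyNA(ord)) stop("region masks do not line up; corrupt plot data",
                       call. = FALSE)
  pd$regions$name <- vals$name[ord]
  pd$regions$members <- vals$members[ord]
  pd$regions$count <- vals$count[ord]
  pd$regions$percent <- vals$percent[ord]
  sz <- set_sizes(venn)
  pd$set_edges$name <- sz$name
  pd$set_edges$set_size <- sz$size
  pd$union_size <- union_size(venn)
  pd
}

check_plot_data <- function(pd) {
  if (!inherits(pd, "venn_plot_data")) {
    stop("expected a `venn_plot_data` object (see build_plot_data())",
         call. = FALSE)
  }
  invisible(pd)
}

#' @export
print.venn_plot_data <- function(x, ...) {
  cat("venn_plot_data:", x$n, "sets,", nrow(x$regions), "regions")
  if (!is.na(x$union_size)) cat(", union size", x$union_size)
  cat("\n")
  if (!is.null(x$metadata$validation_warning)) {
    cat("  warning:", x$metadata$validation_warning, "\n")
  }
  invisible(x)
}

#' Query region members from plot data
#'
#' @param pd A `venn_plot_data` with attached values.
#' @param selector Either a region mask (e.g. `"110"`) or a region name
#'   (e.g. `"A/B"`).
#' @return Character vector of the region's member items.
#' @export
#' @examples
#' v <- make_venn(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' pd <- build_plot_data(v, builtin_layout(2))
#' get_region_items(pd, "11")
#' get_region_items(pd, "A/B")
get_region_items <- function(pd, selector) {
  check_plot_data(pd)
  if (length(selector) != 1L || !is.character(selector)) {
    stop("`selector` must be a single mask or region name", call. = FALSE)
  }
  hit <- which(pd$regions$mask == selector)
  if (!length(hit)) hit <- which(pd$regions$name == selector)
  if (length(hit) != 1L) {
    stop("unknown region '", selector, "'; valid masks: ",
         paste(pd$regions$mask, collapse = ", "), "; valid names: ",
         paste(pd$regions$name, collapse = ", "), call. = FALSE)
  }
  pd$regions$members[[hit]]
}

#' Flat region table
#'
#' One row per region in canonical order: mask, region name, member count,
#' percentage of the union (one decimal, as text), and the members joined by
#' `";"`. Stable across runs.
#'
#' @param pd A `venn_plot_data` with attached values.
#' @return A tibble with columns `mask`, `name`, `count`, `percent`,
#'   `members`.
#' @export
to_region_table <- function(pd) {
  check_plot_data(pd)
  if (anyNA(pd$regions$count)) {
    stop("plot data has no attached values; call attach_sets() first",
         call. = FALSE)
  }
  tibble::tibble(
    mask = pd$regions$mask,
    name = pd$regions$name,
    count = pd$regions$count,
    percent = sprintf("%.1f%%", pd$regions$percent),
    members = vapply(pd$regions$members, paste, character(1), collapse = ";")
  )
}

#' Read and write region tables as TSV
#'
#' UTF-8, header row, columns `mask`, `name`, `count`, `percent`, `members`
#' (members joined by `";"`). `read_region_table()` round-trips a written
#' file into the same tibble.
#'
#' @param tbl A region table (from [to_region_table()]).
#' @param path File path ("" writes TSV to standard output).
#' @return `write_region_table()` returns `path` invisibly;
#'   `read_region_table()` returns a tibble.
#' @export
write_region_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = if (nzchar(path)) "UTF-8" else "")
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "integer", "character",
                                               "character"),
                          fileEncoding = "UTF-8")
  df$members[is.na(df$members)] <- ""
  tibble::as_tibble(df)
}
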