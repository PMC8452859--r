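# Item-level set model: a `venn` collection of 2..7 named sets of distinct
# strings, and the members/counts/percentages of every one of the 2^n - 1
# regions, independent of any geometry.

#' Create a Venn collection of 2 to 7 named sets
#'
#' A `venn` object is the item-level model of a Venn diagram: an ordered
#' sequence of named sets of distinct character items. Items are compared
#' case-sensitively after stripping surrounding whitespace; duplicates within
#' a set are removed on ingest (a message reports how many).
#'
#' @param sets A named list of character vectors. Between 2 and 7 entries;
#'   names must be unique and non-empty.
#' @param quiet If `TRUE`, suppress the de-duplication messages.
#' @return An object of class `venn`: a list with elements `sets` (named list
#'   of deduplicated character vectors), `n` (number of sets) and a
#'   `dedup` attribute counting removed duplicates per set.
#' @export
#' @examples
#' v <- make_venn(list(A = c("a", "b"), B = c("b", "c")))
#' v$n
make_venn <- function(sets, quiet = FALSE) {
  if (!is.list(sets)) stop("`sets` must be a named list of character vectors",
                           call. = FALSE)
  n_try <- length(sets)
  if (n_try < 2L || n_try > 7L) {
    stop("unsupported set count: ", n_try, " (vennkit draws Venn diagrams ",
         "for 2 to 7 sets; for more sets consider an UpSet plot)",
         call. = FALSE)
  }
  nm <- names(sets)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    stop("every set must have a non-empty name", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  dedup <- integer(n_try)
  names(dedup) <- nm
  cleaned <- vector("list", n_try)
  names(cleaned) <- nm
  for (i in seq_len(n_try)) {
    items <- as.character(sets[[i]])
    items <- trimws(items)
    items <- items[!is.na(items) & nzchar(items)]
    kept <- unique(items)
    dedup[i] <- length(items) - length(kept)
    if (dedup[i] > 0L && !quiet) {
      message("set '", nm[i], "': removed ", dedup[i], " duplicate item",
              if (dedup[i] > 1L) "s")
    }
    cleaned[[i]] <- kept
  }
  structure(list(sets = cleaned, n = n_try),
            dedup = dedup, class = "venn")
}

#' @export
print.venn <- function(x, ...) {
  cat("Venn collection of", x$n, "sets:\n")
  for (nm in names(x$sets)) {
    it <- x$sets[[nm]]
    preview <- paste(utils::head(it, 5), collapse = ", ")
    if (length(it) > 5) preview <- paste0(preview, ", ...")
    cat(sprintf("  %s (%d items): %s\n", nm, length(it), preview))
  }
  invisible(x)
}

check_venn <- function(venn) {
  if (!inherits(venn, "venn")) {
    stop("expected a `venn` collection (see make_venn())", call. = FALSE)
  }
  invisible(venn)
}

#' Items belonging to exactly one region of a Venn collection
#'
#' The region identified by a mask contains the items in the intersection of
#' all sets flagged 1, minus the union of all sets flagged 0 — i.e. items
#' that belong to exactly the flagged sets and no others.
#'
#' @param venn A `venn` collection.
#' @param mask A region mask string of length `venn$n`, e.g. `"110"`.
#' @return Character vector of member items.
#' @export
#' @examples
#' v <- make_venn(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' region_members(v, "11")
region_members <- function(venn, mask) {
  check_venn(venn)
  check_mask(mask, n = venn$n)
  bits <- mask_bits(mask)
  inside <- venn$sets[bits == 1L]
  members <- Reduce(intersect, inside)
  outside <- venn$sets[bits == 0L]
  if (length(outside)) {
    members <- setdiff(members, Reduce(union, outside))
  }
  members
}

#' Members, counts and percentages of every region
#'
#' Enumerates all `2^n - 1` regions in canonical order (see [region_masks()]).
#' Every item of the union appears in exactly one region. Percentages are of
#' the union of all sets, rounded half away from zero to one decimal; when
#' the union is empty all percentages are 0.
#'
#' @param venn A `venn` collection.
#' @param sep Separator used to build region names from set names.
#' @return A tibble with columns `mask`, `name`, `members` (list column),
#'   `count` and `percent`.
#' @export
#' @examples
#' v <- make_venn(list(A = "a", B = "b"))
#' all_regions(v)
all_regions <- function(venn, sep = "/") {
  check_venn(venn)
  masks <- region_masks(venn$n)
  members <- lapply(masks, function(m) region_members(venn, m))
  counts <- lengths(members)
  union_size <- length(Reduce(union, venn$sets))
  percents <- if (union_size == 0L) {
    rep(0, length(masks))
  } else {
    round_half_away(100 * counts / union_size, 1L)
  }
  tibble::tibble(
    mask = masks,
    name = vapply(masks, mask_name, character(1),
                  set_names = names(venn$sets), sep = sep,
                  USE.NAMES = FALSE),
    members = members,
    count = as.integer(counts),
    percent = percents
  )
}

#' Sizes of the input sets
#'
#' @param venn A `venn` collection.
#' @return A tibble with columns `name` and `size`, in input order. Sizes are
#'   after de-duplication.
#' @export
set_sizes <- function(venn) {
  check_venn(venn)
  tibble::tibble(name = names(venn$sets),
                 size = as.integer(lengths(venn$sets)))
}

#' Union size of a Venn collection
#'
#' @param venn A `venn` collection.
#' @return Number of distinct items across all sets.
#' @export
union_size <- function(venn) {
  check_venn(venn)
  length(Reduce(union, venn$sets))
}

# Round half away from zero at `digits` decimals (base round() is half-even).
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a region count as a percentage of the union
#'
#' One-decimal percent text with round-half-away-from-zero, e.g.
#' `format_percent(1, 3)` is `"33.3%"`. When `union_size` is 0 the result is
#' `"0.0%"`.
#'
#' @param count Non-negative integer, at most `union_size`.
#' @param union_size Non-negative integer.
#' @return A single string.
#' @export
format_percent <- function(count, union_size) {
  if (length(count) != 1L || length(union_size) != 1L ||
      is.na(count) || is.na(union_size) || count < 0 || union_size < 0) {
    stop("`count` and `union_size` must be single non-negative numbers",
         call. = FALSE)
  }
  if (count > union_size) {
    stop("`count` (", count, ") exceeds `union_size` (", union_size, ")",
         call. = FALSE)
  }
  pct <- if (union_size == 0) 0 else round_half_away(100 * count / union_size, 1L)
  sprintf("%.1f%%", pct)
}
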