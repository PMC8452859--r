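# Synthetic collections with exactly prescribed per-region counts: the
# ground-truth oracle for the whole pipeline. For each mask, fresh unique
# items are minted and added to exactly the sets flagged by the mask, so
# all_regions() on the result must reproduce the prescription.

#' Prescription for a synthetic Venn collection
#'
#' @param n Number of sets, 2..7.
#' @param counts Named numeric vector or list mapping region masks to
#'   non-negative item counts. Absent masks default to 0; unknown masks are
#'   rejected.
#' @param seed Integer seed recorded in the spec (generation itself is
#'   deterministic in the counts; the seed names the provenance of a
#'   randomly drawn spec).
#' @param item_prefix Prefix for minted item names; items are named
#'   `<prefix><mask>_<i>` so mismatches are self-diagnosing.
#' @return An object of class `fixture_spec` with a complete `counts`
#'   vector over all `2^n - 1` masks in canonical order.
#' @export
#' @examples
#' fixture_spec(2, c("11" = 2, "10" = 1))
fixture_spec <- function(n, counts = NULL, seed = 1L, item_prefix = "item") {
  n <- check_set_count(n)
  masks <- region_masks(n)
  full <- stats::setNames(integer(length(masks)), masks)
  if (!is.null(counts)) {
    counts <- unlist(counts)
    bad <- setdiff(names(counts), masks)
    if (length(bad)) {
      stop("unknown mask(s) for n = ", n, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(counts < 0) || any(counts != as.integer(counts))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    full[names(counts)] <- as.integer(counts)
  }
  structure(list(n = n, counts = full, seed = as.integer(seed),
                 item_prefix = item_prefix),
            class = "fixture_spec")
}

#' Generate the Venn collection prescribed by a fixture spec
#'
#' For every mask, `counts[mask]` fresh unique items are created and added
#' to exactly the sets flagged by the mask. The result's [all_regions()]
#' counts equal the prescription exactly, and generation is deterministic.
#'
#' @param spec A `fixture_spec`.
#' @param set_names Optional set names (default `S1..Sn`).
#' @return A `venn` collection.
#' @export
#' @examples
#' v <- generate_fixture(fixture_spec(2, c("11" = 2, "10" = 1)))
#' set_sizes(v)
generate_fixture <- function(spec, set_names = NULL) {
  if (!inherits(spec, "fixture_spec")) {
    stop("expected a `fixture_spec`", call. = FALSE)
  }
  n <- spec$n
  if (is.null(set_names)) set_names <- paste0("S", seq_len(n))
  sets <- stats::setNames(rep(list(character(0)), n), set_names)
  for (mask in names(spec$counts)) {
    k <- spec$counts[[mask]]
    if (k == 0L) next
    items <- sprintf("%s%s_%d", spec$item_prefix, mask, seq_len(k))
    for (i in which(mask_bits(mask) == 1L)) {
      sets[[i]] <- c(sets[[i]], items)
    }
  }
  make_venn(sets, quiet = TRUE)
}

#' Randomly drawn fixture spec
#'
#' Allocates `total_items` across the `2^n - 1` masks by an equal-probability
#' multinomial draw, seeded for reproducibility.
#'
#' @param n Number of sets, 2..7.
#' @param total_items Total number of items to allocate.
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
random_spec <- function(n, total_items, seed = 1L) {
  n <- check_set_count(n)
  if (total_items < 0) stop("`total_items` must be non-negative", call. = FALSE)
  masks <- region_masks(n)
  counts <- with_local_seed(seed,
    as.integer(stats::rmultinom(1L, size = total_items,
                                prob = rep(1, length(masks)))))
  fixture_spec(n, stats::setNames(counts, masks), seed = seed)
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Serialize fixture specs as JSON
#'
#' @param spec A `fixture_spec`.
#' @param path File path.
#' @return `fixture_to_json()` returns `path` invisibly;
#'   `fixture_from_json()` returns a `fixture_spec`.
#' @export
fixture_to_json <- function(spec, path) {
  jsonlite::write_json(
    list(n = spec$n, counts = as.list(spec$counts), seed = spec$seed,
         item_prefix = spec$item_prefix),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname fixture_to_json
#' @export
fixture_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixture_spec(x$n, unlist(x$counts), seed = x$seed,
               item_prefix = x$item_prefix)
}
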