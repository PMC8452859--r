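# Region masks: binary inclusion vectors identifying the 2^n - 1 regions of
# an n-set Venn diagram. A mask is stored as a character string of 0/1, bit i
# giving membership of the i-th input set. Masks are the unique join IDs
# between the item-level set algebra and the layout geometry.

#' Enumerate all region masks of an n-set Venn diagram in canonical order
#'
#' A Venn diagram of `n` sets has `2^n - 1` regions, one per non-zero
#' inclusion mask. The canonical order used throughout vennkit is:
#' ascending number of included sets, ties broken by the lexicographic order
#' of the tuple of included set indices. For `n = 3` this gives
#' `"100", "010", "001", "110", "101", "011", "111"`.
#'
#' @param n Number of sets, an integer in 2..7.
#' @return Character vector of `2^n - 1` masks.
#' @export
#' @examples
#' region_masks(2)
region_masks <- function(n) {
  n <- check_set_count(n)
  vals <- seq_len(2^n - 1L)
  bits <- vapply(vals, function(v) as.integer(intToBits(v))[seq_len(n)], integer(n))
  bits <- matrix(bits, nrow = n) # column per value; bit 1 = set 1
  pop <- colSums(bits)
  # mask as binary number with set 1 as the most significant bit; descending
  # numeric value within a popcount class == ascending index-tuple order
  num <- as.vector(2^((n - 1):0) %*% bits)
  ord <- order(pop, -num)
  apply(bits[, ord, drop = FALSE], 2, paste, collapse = "")
}

#' Convert between mask strings and bit vectors
#'
#' @param mask A mask string such as `"101"`.
#' @return `mask_bits()` returns an integer vector of 0/1;
#'   `mask_from_bits()` returns the mask string.
#' @export
#' @examples
#' mask_bits("101")
#' mask_from_bits(c(1, 0, 1))
mask_bits <- function(mask) {
  check_mask(mask)
  as.integer(strsplit(mask, "", fixed = TRUE)[[1]])
}

#' @rdname mask_bits
#' @param bits Integer vector of 0s and 1s.
#' @export
mask_from_bits <- function(bits) {
  if (!length(bits) || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must be a non-empty vector of 0s and 1s", call. = FALSE)
  }
  paste(as.integer(bits), collapse = "")
}

#' Human-readable region name for a mask
#'
#' The name of a region is the names of its included sets joined by a
#' separator, e.g. mask `"110"` over sets A, B, C is `"A/B"`.
#'
#' @param mask Mask string.
#' @param set_names Character vector of set names, one per bit.
#' @param sep Separator between included set names.
#' @return A single string.
#' @export
mask_name <- function(mask, set_names, sep = "/") {
  bits <- mask_bits(mask)
  if (length(bits) != length(set_names)) {
    stop("mask length does not match the number of set names", call. = FALSE)
  }
  paste(set_names[bits == 1L], collapse = sep)
}

check_mask <- function(mask, n = NULL) {
  if (!is.character(mask) || length(mask) != 1L || is.na(mask) ||
      !grepl("^[01]+$", mask)) {
    stop("a region mask must be a single string of 0s and 1s", call. = FALSE)
  }
  if (!grepl("1", mask, fixed = TRUE)) {
    stop("the all-zero mask does not identify a region", call. = FALSE)
  }
  if (!is.null(n) && nchar(mask) != n) {
    stop(sprintf("mask '%s' has %d bits but the collection has %d sets",
                 mask, nchar(mask), n), call. = FALSE)
  }
  invisible(mask)
}

check_set_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n != as.integer(n)) {
    stop("`n` must be a single integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 2L || n > 7L) {
    stop("unsupported set count: ", n, " (vennkit draws Venn diagrams for ",
         "2 to 7 sets; for more sets consider an UpSet plot)", call. = FALSE)
  }
  n
}
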