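# Geometric region computation: decompose a layout's n shapes into the
# 2^n - 1 Venn regions (one per non-zero mask), validate that a layout is a
# true Venn diagram, and place interior label anchors.

#' Compute the geometric regions of a layout
#'
#' The region for mask m is the intersection of all shapes flagged 1 minus
#' the union of all shapes flagged 0. Computed by incremental cell
#' decomposition: each shape in turn splits every existing cell into its
#' inside and outside part, which costs about `2^(n+1)` boolean operations
#' instead of `n * 2^n` when each mask is computed from scratch.
#'
#' @param layout A `shape_layout`.
#' @return A tibble with one row per non-zero mask in canonical order:
#'   columns `mask`, `poly` (list of `poly_shape`), `area`, and `empty`
#'   (TRUE when the region has no geometry).
#' @export
#' @examples
#' compute_regions(builtin_layout(2))
compute_regions <- function(layout) {
  check_layout(layout)
  n <- layout$n
  cells <- list()       # named by mask prefix, only non-empty cells kept
  u <- NULL             # union of shapes seen so far
  for (k in seq_len(n)) {
    s <- layout$shapes[[k]]
    nxt <- list()
    for (m in names(cells)) {
      p <- cells[[m]]
      pin <- poly_intersect(p, s)
      pout <- poly_difference(p, s)
      if (!poly_is_empty(pin)) nxt[[paste0(m, "1")]] <- pin
      if (!poly_is_empty(pout)) nxt[[paste0(m, "0")]] <- pout
    }
    fresh <- if (k == 1L) s else poly_difference(s, u)
    if (!poly_is_empty(fresh)) {
      nxt[[paste0(strrep("0", k - 1L), "1")]] <- fresh
    }
    u <- if (k == 1L) s else poly_union(u, s)
    cells <- nxt
  }
  masks <- region_masks(n)
  polys <- lapply(masks, function(m) {
    p <- cells[[m]]
    if (is.null(p)) poly_empty() else p
  })
  tibble::tibble(
    mask = masks,
    poly = polys,
    area = vapply(polys, poly_area, numeric(1)),
    empty = vapply(polys, poly_is_empty, logical(1))
  )
}

#' Validate that a layout is a complete Venn diagram
#'
#' A valid n-set layout must decompose into exactly `2^n - 1` regions of
#' positive area that are pairwise disjoint and together tile the union of
#' all shapes. The report measures each property: the count of positive-area
#' regions, the maximum pairwise region-overlap area, and the absolute
#' difference between the summed region areas and the union area. All
#' comparisons use `eps = eps_rel * union area` (default `eps_rel = 1e-6`).
#'
#' @param layout A `shape_layout`.
#' @param regions Optional precomputed result of [compute_regions()] for
#'   this layout (avoids recomputing).
#' @param eps_rel Relative tolerance.
#' @return A list of class `venn_layout_report`: fields `n`,
#'   `expected_regions`, `positive_regions`, `max_pairwise_overlap`,
#'   `area_discrepancy`, `union_area`, `eps`, `region_areas` (named by
#'   mask) and `valid`.
#' @export
validate_layout <- function(layout, regions = NULL, eps_rel = 1e-6) {
  check_layout(layout)
  if (is.null(regions)) regions <- compute_regions(layout)
  u <- Reduce(poly_union, layout$shapes)
  union_area <- poly_area(u)
  eps <- eps_rel * union_area
  pos <- regions$area > eps
  # pairwise overlaps among positive regions, bbox-filtered
  max_ov <- 0
  ip <- which(pos)
  if (length(ip) > 1L) {
    bbs <- t(vapply(regions$poly[ip], poly_bbox, numeric(4)))
    for (ii in seq_along(ip)[-length(ip)]) {
      for (jj in seq.int(ii + 1L, length(ip))) {
        if (bbs[ii, 3L] < bbs[jj, 1L] || bbs[jj, 3L] < bbs[ii, 1L] ||
            bbs[ii, 4L] < bbs[jj, 2L] || bbs[jj, 4L] < bbs[ii, 2L]) next
        ov <- poly_area(poly_intersect(regions$poly[[ip[ii]]],
                                       regions$poly[[ip[jj]]]))
        if (ov > max_ov) max_ov <- ov
      }
    }
  }
  discrepancy <- abs(sum(regions$area) - union_area)
  areas <- stats::setNames(regions$area, regions$mask)
  expected <- as.integer(2^layout$n - 1)
  structure(list(
    n = layout$n,
    expected_regions = expected,
    positive_regions = sum(pos),
    max_pairwise_overlap = max_ov,
    area_discrepancy = discrepancy,
    union_area = union_area,
    eps = eps,
    region_areas = areas,
    valid = sum(pos) == expected && max_ov < eps && discrepancy < eps
  ), class = "venn_layout_report")
}

#' @export
print.venn_layout_report <- function(x, ...) {
  cat("Layout validation (", x$n, " sets)\n", sep = "")
  cat(sprintf("  positive-area regions: %d / %d expected\n",
              x$positive_regions, x$expected_regions))
  cat(sprintf("  max pairwise overlap:  %.3g (eps = %.3g)\n",
              x$max_pairwise_overlap, x$eps))
  cat(sprintf("  |sum areas - union|:   %.3g\n", x$area_discrepancy))
  cat("  valid:", x$valid, "\n")
  invisible(x)
}

#' Interior label anchor of a region polygon
#'
#' Approximates the pole of inaccessibility (the interior point farthest
#' from the boundary) of the largest part of the polygon by a deterministic
#' coarse-to-fine grid search. Robust for crescent-shaped regions where the
#' centroid falls outside.
#'
#' @param poly A `poly_shape` with positive area.
#' @return Numeric length-2 point strictly inside the polygon, or `NULL`
#'   for an empty polygon (callers skip the label).
#' @export
region_label_anchor <- function(poly) {
  check_poly(poly)
  if (poly_is_empty(poly) || poly_area(poly) <= 0) return(NULL)
  part <- largest_part(poly)
  segs <- poly_segments(part)
  bb <- poly_bbox(part)
  # level 0: coarse grid over the part's bounding box
  best <- NULL; best_d <- -Inf
  span <- max(bb[3L] - bb[1L], bb[4L] - bb[2L])
  gx <- seq(bb[1L], bb[3L], length.out = 24L)
  gy <- seq(bb[2L], bb[4L], length.out = 24L)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  for (level in 1:3) {
    inside <- poly_winding(pts[, 1L], pts[, 2L], part) != 0L
    if (any(inside)) {
      d <- dist_to_segments(pts[inside, , drop = FALSE], segs)
      k <- which.max(d)
      if (d[k] > best_d) {
        best_d <- d[k]
        best <- pts[inside, , drop = FALSE][k, ]
      }
    }
    if (level == 3L || is.null(best)) break
    h <- span / (2^(level + 2L))  # refine around the current best
    gx <- seq(best[1L] - h, best[1L] + h, length.out = 12L)
    gy <- seq(best[2L] - h, best[2L] + h, length.out = 12L)
    pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  }
  if (is.null(best)) {
    # extremely thin region: fall back to the midpoint of a boundary edge
    # nudged inward
    mids <- cbind((segs[, 1L] + segs[, 3L]) / 2, (segs[, 2L] + segs[, 4L]) / 2)
    nx <- -(segs[, 4L] - segs[, 2L]); ny <- segs[, 3L] - segs[, 1L]
    l <- sqrt(nx^2 + ny^2)
    for (off in c(1e-4, 1e-5, 1e-6)) {
      cand <- cbind(mids[, 1L] - off * nx / l, mids[, 2L] - off * ny / l)
      ok <- poly_winding(cand[, 1L], cand[, 2L], part) != 0L
      if (any(ok)) return(as.numeric(cand[which(ok)[1L], ]))
    }
    return(as.numeric(mids[1L, ]))
  }
  as.numeric(best)
}

# outer ring with the largest enclosed area, together with its holes
largest_part <- function(poly) {
  areas <- vapply(poly$rings, ring_signed_area, numeric(1))
  outers <- which(areas > 0)
  if (length(outers) <= 1L && length(poly$rings) <= 1L) return(poly)
  if (!length(outers)) return(poly)
  holes <- which(areas < 0)
  hole_net <- numeric(length(outers))
  assign_to <- integer(length(holes))
  for (hi in seq_along(holes)) {
    pt <- ring_open(poly$rings[[holes[hi]]])[1L, , drop = FALSE]
    for (oi in seq_along(outers)) {
      if (point_in_poly(pt, new_poly(poly$rings[outers[oi]]))) {
        assign_to[hi] <- oi
        hole_net[oi] <- hole_net[oi] + areas[holes[hi]]
        break
      }
    }
  }
  net <- areas[outers] + hole_net
  pick <- which.max(net)
  new_poly(c(poly$rings[outers[pick]],
             poly$rings[holes[assign_to == pick]]))
}

# min distance from each point to any segment
dist_to_segments <- function(pts, segs) {
  d <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(segs))) {
    x0 <- segs[k, 1L]; y0 <- segs[k, 2L]
    dx <- segs[k, 3L] - x0; dy <- segs[k, 4L] - y0
    l2 <- dx^2 + dy^2
    if (l2 == 0) {
      dk <- sqrt((pts[, 1L] - x0)^2 + (pts[, 2L] - y0)^2)
    } else {
      t <- pmin(1, pmax(0, ((pts[, 1L] - x0) * dx + (pts[, 2L] - y0) * dy) / l2))
      dk <- sqrt((pts[, 1L] - x0 - t * dx)^2 + (pts[, 2L] - y0 - t * dy)^2)
    }
    d <- pmin(d, dk)
  }
  d
}
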