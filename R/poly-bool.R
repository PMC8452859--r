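# Polygon boolean operations (intersection, union, difference) on
# `poly_shape` objects, mirroring the item-level set operations so shapes and
# item sets share one algebra.
#
# Algorithm: segment classification. Both boundaries are split at every
# mutual crossing (collinear overlaps are split at each other's endpoints so
# coincident portions become exactly equal sub-segments). Each sub-segment is
# then classified as inside/outside the other shape (midpoint winding
# number) or as coincident with an equal/opposite-direction partner, the
# rule table for the requested operation selects which directed sub-segments
# survive, and the survivors are stitched back into closed rings (sharpest
# left turn at junctions, which yields simple rings and interior-on-the-left
# orientation: outer rings CCW, holes CW).
#
# Coordinates are snapped to the shared 2^-30 grid, so geometry that is
# genuinely coincident (a repeated shape, a shared frame edge) compares
# exactly equal and the degenerate cases (a minus a, union with itself,
# adjacent shapes sharing an edge) resolve without epsilon games.

# relative tolerance for parallel / collinear tests
BOOL_PAR_TOL <- 1e-9
# output rings (slivers) below this absolute area are discarded
BOOL_SLIVER_EPS <- 1e-9

#' Boolean operations on polygon shapes
#'
#' `poly_intersect(a, b)` is the region covered by both shapes,
#' `poly_union(a, b)` by either, and `poly_difference(a, b)` by `a` but not
#' `b` — the same semantics as the item-level `intersect`/`union`/`setdiff`
#' on sets. Results are exact up to vertex discretization; an empty result is
#' a valid zero-area shape. Degenerate slivers (area below `1e-9` square
#' units) are dropped.
#'
#' @param a,b `poly_shape` objects with clean (non-self-intersecting) rings.
#' @return A `poly_shape`, possibly empty or multi-part (with holes).
#' @export
#' @examples
#' a <- circle(c(0, 0), 1)
#' b <- circle(c(1, 0), 1)
#' poly_area(poly_intersect(a, b))  # lens area, about 1.228
poly_intersect <- function(a, b) poly_bool(a, b, "intersection")

#' @rdname poly_intersect
#' @export
poly_union <- function(a, b) poly_bool(a, b, "union")

#' @rdname poly_intersect
#' @export
poly_difference <- function(a, b) poly_bool(a, b, "difference")

poly_bool <- function(a, b, op) {
  check_poly(a); check_poly(b)
  ensure_clean(a); ensure_clean(b)
  if (poly_is_empty(a)) {
    return(switch(op, intersection = poly_empty(), union = b,
                  difference = poly_empty()))
  }
  if (poly_is_empty(b)) {
    return(switch(op, intersection = poly_empty(), union = a,
                  difference = a))
  }
  # fast path: disjoint bounding boxes
  ba <- poly_bbox(a); bb <- poly_bbox(b)
  if (ba[3L] < bb[1L] || bb[3L] < ba[1L] || ba[4L] < bb[2L] || bb[4L] < ba[2L]) {
    return(switch(op,
      intersection = poly_empty(),
      union = new_poly(c(a$rings, b$rings)),
      difference = a))
  }

  segsA <- poly_segments(a)
  segsB <- poly_segments(b)
  sp <- split_mutual(segsA, segsB)
  subA <- sp$A; subB <- sp$B

  keyf <- function(m) paste(m[, 1L], m[, 2L], m[, 3L], m[, 4L], sep = "|")
  keyr <- function(m) paste(m[, 3L], m[, 4L], m[, 1L], m[, 2L], sep = "|")
  kA <- keyf(subA); kAr <- keyr(subA)
  kB <- keyf(subB); kBr <- keyr(subB)
  A_same <- kA %in% kB       # coincident, same direction
  A_opp <- kA %in% kBr       # coincident, opposite direction
  B_coinc <- kB %in% kA | kB %in% kAr

  insideB <- seg_inside(subA, b, skip = A_same | A_opp)
  insideA <- seg_inside(subB, a, skip = B_coinc)

  keep <- switch(op,
    intersection = {
      ka <- subA[A_same | (!A_opp & !A_same & insideB), , drop = FALSE]
      kb <- subB[!B_coinc & insideA, , drop = FALSE]
      rbind(ka, kb)
    },
    union = {
      ka <- subA[A_same | (!A_opp & !A_same & !insideB), , drop = FALSE]
      kb <- subB[!B_coinc & !insideA, , drop = FALSE]
      rbind(ka, kb)
    },
    difference = {
      ka <- subA[A_opp | (!A_opp & !A_same & !insideB), , drop = FALSE]
      kb <- subB[!B_coinc & insideA, , drop = FALSE]
      if (nrow(kb)) kb <- kb[, c(3L, 4L, 1L, 2L), drop = FALSE]  # reversed
      rbind(ka, kb)
    })
  if (!nrow(keep)) return(poly_empty())
  rings <- stitch_rings(keep)
  if (!length(rings)) return(poly_empty())
  new_poly(rings)
}

ensure_clean <- function(p) {
  if (isTRUE(attr(p, "clean"))) return(invisible(TRUE))
  for (i in seq_along(p$rings)) {
    check_ring_simple(ring_open(p$rings[[i]]), i)
  }
  invisible(TRUE)
}

# Split the segments of A and B at all mutual intersections (including
# endpoints of collinear overlaps). Returns list(A=, B=) of segment matrices.
split_mutual <- function(segsA, segsB) {
  nA <- nrow(segsA); nB <- nrow(segsB)
  ax0 <- pmin(segsA[, 1L], segsA[, 3L]); ax1 <- pmax(segsA[, 1L], segsA[, 3L])
  ay0 <- pmin(segsA[, 2L], segsA[, 4L]); ay1 <- pmax(segsA[, 2L], segsA[, 4L])
  bx0 <- pmin(segsB[, 1L], segsB[, 3L]); bx1 <- pmax(segsB[, 1L], segsB[, 3L])
  by0 <- pmin(segsB[, 2L], segsB[, 4L]); by1 <- pmax(segsB[, 2L], segsB[, 4L])

  # candidate pairs by bbox overlap (with a hair of slack)
  sl <- 1e-9
  ov <- outer(ax0, bx1 + sl, `<=`) & outer(ax1 + sl, bx0, `>=`) &
        outer(ay0, by1 + sl, `<=`) & outer(ay1 + sl, by0, `>=`)
  idx <- which(ov, arr.ind = TRUE)
  splitsA <- vector("list", nA)
  splitsB <- vector("list", nB)
  if (nrow(idx)) {
    i <- idx[, 1L]; j <- idx[, 2L]
    Ax0 <- segsA[i, 1L]; Ay0 <- segsA[i, 2L]
    rx <- segsA[i, 3L] - Ax0; ry <- segsA[i, 4L] - Ay0
    Bx0 <- segsB[j, 1L]; By0 <- segsB[j, 2L]
    sx <- segsB[j, 3L] - Bx0; sy <- segsB[j, 4L] - By0
    den <- rx * sy - ry * sx
    qx <- Bx0 - Ax0; qy <- By0 - Ay0
    la <- sqrt(rx^2 + ry^2); lb <- sqrt(sx^2 + sy^2)
    par <- abs(den) <= BOOL_PAR_TOL * la * lb
    col <- par & abs(qx * ry - qy * rx) <= BOOL_PAR_TOL * la * la

    # transversal crossings
    tr <- which(!par)
    if (length(tr)) {
      tt <- (qx[tr] * sy[tr] - qy[tr] * sx[tr]) / den[tr]
      uu <- (qx[tr] * ry[tr] - qy[tr] * rx[tr]) / den[tr]
      okt <- tt >= -1e-9 & tt <= 1 + 1e-9 & uu >= -1e-9 & uu <= 1 + 1e-9
      tr <- tr[okt]; tt <- tt[okt]
      if (length(tr)) {
        px <- snap_coords(Ax0[tr] + tt * rx[tr])
        py <- snap_coords(Ay0[tr] + tt * ry[tr])
        for (k in seq_along(tr)) {
          ii <- i[tr[k]]; jj <- j[tr[k]]
          splitsA[[ii]] <- c(splitsA[[ii]], px[k], py[k])
          splitsB[[jj]] <- c(splitsB[[jj]], px[k], py[k])
        }
      }
    }
    # collinear overlaps: split each segment at the other's endpoints
    co <- which(col)
    for (k in co) {
      ii <- i[k]; jj <- j[k]
      l2 <- rx[k]^2 + ry[k]^2
      for (pt in list(c(segsB[jj, 1L], segsB[jj, 2L]),
                      c(segsB[jj, 3L], segsB[jj, 4L]))) {
        t <- ((pt[1L] - Ax0[k]) * rx[k] + (pt[2L] - Ay0[k]) * ry[k]) / l2
        if (t > 1e-12 && t < 1 - 1e-12) {
          splitsA[[ii]] <- c(splitsA[[ii]], pt[1L], pt[2L])
        }
      }
      m2 <- sx[k]^2 + sy[k]^2
      for (pt in list(c(segsA[ii, 1L], segsA[ii, 2L]),
                      c(segsA[ii, 3L], segsA[ii, 4L]))) {
        u <- ((pt[1L] - Bx0[k]) * sx[k] + (pt[2L] - By0[k]) * sy[k]) / m2
        if (u > 1e-12 && u < 1 - 1e-12) {
          splitsB[[jj]] <- c(splitsB[[jj]], pt[1L], pt[2L])
        }
      }
    }
  }
  list(A = apply_splits(segsA, splitsA), B = apply_splits(segsB, splitsB))
}

apply_splits <- function(segs, splits) {
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    pts <- splits[[i]]
    if (is.null(pts)) {
      if (s[1L] != s[3L] || s[2L] != s[4L]) out[[i]] <- matrix(s, nrow = 1L)
      next
    }
    pm <- matrix(pts, ncol = 2L, byrow = TRUE)
    dx <- s[3L] - s[1L]; dy <- s[4L] - s[2L]
    tt <- ((pm[, 1L] - s[1L]) * dx + (pm[, 2L] - s[2L]) * dy) / (dx^2 + dy^2)
    ord <- order(tt)
    chain <- rbind(c(s[1L], s[2L]), pm[ord, , drop = FALSE], c(s[3L], s[4L]))
    keep <- c(TRUE, rowSums(abs(diff(chain))) > 0)
    chain <- chain[keep, , drop = FALSE]
    m <- nrow(chain)
    if (m < 2L) next
    out[[i]] <- cbind(chain[-m, 1L], chain[-m, 2L], chain[-1L, 1L], chain[-1L, 2L])
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 4L)
  m
}

# classify sub-segments by midpoint winding number w.r.t. `other`;
# entries flagged in `skip` (coincident) and those outside the bbox are FALSE
seg_inside <- function(subs, other, skip) {
  n <- nrow(subs)
  inside <- logical(n)
  if (!n) return(inside)
  bb <- poly_bbox(other)
  mx <- (subs[, 1L] + subs[, 3L]) / 2
  my <- (subs[, 2L] + subs[, 4L]) / 2
  cand <- !skip & mx >= bb[1L] & mx <= bb[3L] & my >= bb[2L] & my <= bb[4L]
  if (any(cand)) {
    inside[cand] <- poly_winding(mx[cand], my[cand], other) != 0L
  }
  inside
}

# stitch directed segments into closed rings; at junctions take the
# sharpest left turn (interior stays on the left)
stitch_rings <- function(segs) {
  # drop exact duplicate directed segments
  key <- paste(segs[, 1L], segs[, 2L], segs[, 3L], segs[, 4L], sep = "|")
  segs <- segs[!duplicated(key), , drop = FALSE]
  n <- nrow(segs)
  if (!n) return(list())
  ord <- order(segs[, 1L], segs[, 2L], segs[, 3L], segs[, 4L])
  segs <- segs[ord, , drop = FALSE]
  fromk <- paste(segs[, 1L], segs[, 2L], sep = "|")
  out_idx <- split(seq_len(n), fromk)
  used <- logical(n)
  rings <- list()
  ang <- atan2(segs[, 4L] - segs[, 2L], segs[, 3L] - segs[, 1L])
  for (start in seq_len(n)) {
    if (used[start]) next
    path <- integer(0)
    cur <- start
    repeat {
      used[cur] <- TRUE
      path <- c(path, cur)
      if (segs[cur, 3L] == segs[start, 1L] &&
          segs[cur, 4L] == segs[start, 2L]) {
        if (length(path) >= 3L) {
          r <- rbind(segs[path, 1:2, drop = FALSE],
                     segs[cur, 3:4, drop = FALSE])
          if (abs(ring_signed_area(r)) >= BOOL_SLIVER_EPS) {
            rings[[length(rings) + 1L]] <- r
          }
        }
        break
      }
      endk <- paste(segs[cur, 3L], segs[cur, 4L], sep = "|")
      cands <- out_idx[[endk]]
      cands <- cands[!used[cands]]
      if (is.null(cands) || !length(cands)) break  # open path: discard
      if (length(cands) == 1L) {
        cur <- cands
      } else {
        rel <- (ang[cands] - ang[cur]) %% (2 * pi)
        rel[rel < 1e-12] <- 2 * pi  # straight ahead is the last resort
        cur <- cands[which.min(rel)]
      }
    }
  }
  rings
}
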