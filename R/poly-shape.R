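# Polygon primitives. A `poly_shape` is one or more closed rings of planar
# vertices in abstract plot units (nominal [0,1] x [0,1] frame, y upward).
# Rings are stored explicitly closed (first vertex repeated last), outer
# rings counter-clockwise (positive signed area) and holes clockwise, so the
# area of a shape is the sum of signed ring areas (non-zero winding rule).
#
# All coordinates are snapped to a 2^-30 grid on ingest. This makes
# genuinely coincident geometry (shared edges, repeated shapes) exactly
# equal, which the boolean engine relies on to resolve degenerate overlaps.

SNAP_GRID <- 2^30

snap_coords <- function(x) round(x * SNAP_GRID) / SNAP_GRID

#' Construct a polygon shape from rings of vertices
#'
#' @param rings A single two-column matrix, or a list of two-column matrices
#'   (columns x, y). Each ring needs at least 3 distinct vertices; closure is
#'   enforced (the first vertex is repeated at the end if absent).
#' @param check If `TRUE`, reject rings that self-intersect.
#' @param orient If `TRUE`, orient rings by even-odd containment: rings
#'   contained in an odd number of other rings become holes (clockwise), the
#'   rest outer boundaries (counter-clockwise).
#' @return An object of class `poly_shape`.
#' @export
#' @examples
#' sq <- poly_shape(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' poly_area(sq)
poly_shape <- function(rings, check = TRUE, orient = TRUE) {
  if (is.matrix(rings) || is.data.frame(rings)) rings <- list(as.matrix(rings))
  if (!is.list(rings)) stop("`rings` must be a matrix or a list of matrices",
                            call. = FALSE)
  cleaned <- list()
  for (i in seq_along(rings)) {
    r <- as.matrix(rings[[i]])
    if (ncol(r) != 2L || !is.numeric(r) || any(!is.finite(r))) {
      stop("ring ", i, ": vertices must be a two-column matrix of finite ",
           "numbers", call. = FALSE)
    }
    r <- snap_coords(r)
    r <- ring_dedup(r)
    if (nrow(r) < 3L) next            # degenerate after cleaning
    if (check) check_ring_simple(r, i)
    if (abs(ring_signed_area(r)) < 1e-12) next
    cleaned[[length(cleaned) + 1L]] <- ring_close(r)
  }
  p <- structure(list(rings = cleaned), class = "poly_shape", clean = TRUE)
  if (orient && length(cleaned) > 1L) p <- orient_rings(p)
  if (orient && length(cleaned) == 1L && ring_signed_area(cleaned[[1]]) < 0) {
    p$rings[[1]] <- ring_reverse(p$rings[[1]])
  }
  p
}

# fast internal constructor for engine output (already snapped/oriented)
new_poly <- function(rings) {
  structure(list(rings = rings), class = "poly_shape", clean = TRUE)
}

#' An empty polygon shape
#' @return A `poly_shape` with no rings and zero area.
#' @export
poly_empty <- function() new_poly(list())

#' Test whether a shape has no geometry
#' @param p A `poly_shape`.
#' @return Logical.
#' @export
poly_is_empty <- function(p) length(p$rings) == 0L

check_poly <- function(p) {
  if (!inherits(p, "poly_shape")) {
    stop("expected a `poly_shape` object", call. = FALSE)
  }
  invisible(p)
}

# -- ring helpers (rings are closed matrices) ------------------------------

ring_close <- function(r) {
  if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, ])
  r
}

ring_open <- function(r) {
  if (nrow(r) > 1L && all(r[1L, ] == r[nrow(r), ])) r[-nrow(r), , drop = FALSE] else r
}

# drop consecutive duplicate vertices (and trailing closure vertex)
ring_dedup <- function(r) {
  r <- ring_open(r)
  if (nrow(r) < 2L) return(r)
  keep <- c(TRUE, rowSums(abs(diff(r))) > 0)
  r[keep, , drop = FALSE]
}

ring_reverse <- function(r) r[nrow(r):1L, , drop = FALSE]

ring_signed_area <- function(r) {
  r <- ring_open(r)
  n <- nrow(r)
  if (n < 3L) return(0)
  x <- r[, 1L]; y <- r[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Area of a polygon shape
#'
#' Sum of signed ring areas: holes (clockwise rings) subtract.
#'
#' @param p A `poly_shape`.
#' @return A non-negative number (0 for an empty shape).
#' @export
poly_area <- function(p) {
  check_poly(p)
  if (poly_is_empty(p)) return(0)
  a <- sum(vapply(p$rings, ring_signed_area, numeric(1)))
  max(a, 0)
}

poly_bbox <- function(p) {
  if (poly_is_empty(p)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  xs <- unlist(lapply(p$rings, function(r) r[, 1L]))
  ys <- unlist(lapply(p$rings, function(r) r[, 2L]))
  c(min(xs), min(ys), max(xs), max(ys))
}

# all directed segments of a shape: matrix x0 y0 x1 y1
poly_segments <- function(p) {
  segs <- lapply(p$rings, function(r) {
    n <- nrow(r)
    cbind(r[-n, 1L], r[-n, 2L], r[-1L, 1L], r[-1L, 2L])
  })
  m <- do.call(rbind, segs)
  colnames(m) <- c("x0", "y0", "x1", "y1")
  m
}

# winding number of points w.r.t. the rings of p (non-zero rule)
poly_winding <- function(px, py, p) {
  wn <- integer(length(px))
  if (poly_is_empty(p)) return(wn)
  segs <- poly_segments(p)
  for (k in seq_len(nrow(segs))) {
    x0 <- segs[k, 1L]; y0 <- segs[k, 2L]; x1 <- segs[k, 3L]; y1 <- segs[k, 4L]
    crs <- (x1 - x0) * (py - y0) - (y1 - y0) * (px - x0)
    up <- (y0 <= py) & (y1 > py) & (crs > 0)
    dn <- (y1 <= py) & (y0 > py) & (crs < 0)
    wn <- wn + up - dn
  }
  wn
}

#' Point-in-polygon test
#'
#' Non-zero winding rule; points exactly on the boundary may fall on either
#' side at numeric resolution.
#'
#' @param points A two-column matrix of point coordinates.
#' @param p A `poly_shape`.
#' @return Logical vector, one entry per point.
#' @export
point_in_poly <- function(points, p) {
  check_poly(p)
  points <- matrix(as.numeric(points), ncol = 2L)
  poly_winding(points[, 1L], points[, 2L], p) != 0L
}

# proper self-intersection check for one open ring
check_ring_simple <- function(r, ring_id) {
  n <- nrow(r)
  if (n < 4L) return(invisible(TRUE))
  rc <- ring_close(r)
  x0 <- rc[-nrow(rc), 1L]; y0 <- rc[-nrow(rc), 2L]
  x1 <- rc[-1L, 1L];       y1 <- rc[-1L, 2L]
  m <- length(x0)
  for (i in seq_len(m - 2L)) {
    j <- seq.int(i + 2L, m)
    j <- j[!(i == 1L & j == m)]     # skip the two neighbours of segment i
    if (!length(j)) next
    rx <- x1[i] - x0[i]; ry <- y1[i] - y0[i]
    sx <- x1[j] - x0[j]; sy <- y1[j] - y0[j]
    den <- rx * sy - ry * sx
    qx <- x0[j] - x0[i]; qy <- y0[j] - y0[i]
    tt <- (qx * sy - qy * sx) / den
    uu <- (qx * ry - qy * rx) / den
    bad <- abs(den) > 1e-14 & tt > 1e-9 & tt < 1 - 1e-9 & uu > 1e-9 & uu < 1 - 1e-9
    if (any(bad, na.rm = TRUE)) {
      stop("ring ", ring_id, " is self-intersecting; clean the input shape",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# even-odd containment orientation for multi-ring ingest
orient_rings <- function(p) {
  k <- length(p$rings)
  depth <- integer(k)
  for (i in seq_len(k)) {
    pt <- ring_open(p$rings[[i]])[1L, , drop = FALSE]
    for (j in seq_len(k)) {
      if (i == j) next
      if (point_in_poly(pt, new_poly(p$rings[j]))) depth[i] <- depth[i] + 1L
    }
  }
  for (i in seq_len(k)) {
    a <- ring_signed_area(p$rings[[i]])
    want_ccw <- depth[i] %% 2L == 0L
    if ((want_ccw && a < 0) || (!want_ccw && a > 0)) {
      p$rings[[i]] <- ring_reverse(p$rings[[i]])
    }
  }
  p
}

# -- transforms ------------------------------------------------------------

#' Affine transforms of polygon shapes
#'
#' @param p A `poly_shape`.
#' @param dx,dy Translation offsets.
#' @param deg Rotation angle in degrees, counter-clockwise.
#' @param center Point the rotation/scaling is applied about.
#' @param sx,sy Scale factors.
#' @return A transformed `poly_shape`.
#' @export
poly_translate <- function(p, dx, dy) {
  check_poly(p)
  new_poly(lapply(p$rings, function(r) snap_coords(cbind(r[, 1L] + dx, r[, 2L] + dy))))
}

#' @rdname poly_translate
#' @export
poly_rotate <- function(p, deg, center = c(0.5, 0.5)) {
  check_poly(p)
  th <- deg * pi / 180
  co <- cos(th); si <- sin(th)
  new_poly(lapply(p$rings, function(r) {
    x <- r[, 1L] - center[1L]; y <- r[, 2L] - center[2L]
    snap_coords(cbind(center[1L] + co * x - si * y,
                      center[2L] + si * x + co * y))
  }))
}

#' @rdname poly_translate
#' @export
poly_scale <- function(p, sx, sy = sx, center = c(0.5, 0.5)) {
  check_poly(p)
  rings <- lapply(p$rings, function(r) {
    snap_coords(cbind(center[1L] + (r[, 1L] - center[1L]) * sx,
                      center[2L] + (r[, 2L] - center[2L]) * sy))
  })
  if (sx * sy < 0) rings <- lapply(rings, ring_reverse)
  new_poly(rings)
}

#' @export
print.poly_shape <- function(x, ...) {
  cat("poly_shape:", length(x$rings), "ring(s), area",
      format(poly_area(x), digits = 6), "\n")
  invisible(x)
}

# -- primitives ------------------------------------------------------------

#' Discretized circle
#'
#' @param center Numeric length-2 center point.
#' @param radius Positive radius.
#' @param n_vertices Number of vertices (>= 32 recommended; default 720 per
#'   full turn, the package-wide smooth-curve resolution).
#' @return A `poly_shape` with one counter-clockwise ring.
#' @export
#' @examples
#' abs(poly_area(circle(c(0, 0), 1, 3600)) - pi) < 1e-4
circle <- function(center, radius, n_vertices = 720) {
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  if (n_vertices < 3L) stop("`n_vertices` must be at least 3", call. = FALSE)
  th <- 2 * pi * seq(0L, n_vertices - 1L) / n_vertices
  poly_shape(cbind(center[1L] + radius * cos(th),
                   center[2L] + radius * sin(th)),
             check = FALSE, orient = FALSE)
}

#' Discretized rotated ellipse
#'
#' @param center Numeric length-2 center point.
#' @param semi_axes Numeric length-2 `(a, b)` semi-axis lengths, both > 0.
#' @param rotation_deg Rotation in degrees, counter-clockwise.
#' @param n_vertices Number of vertices.
#' @return A `poly_shape`.
#' @export
ellipse <- function(center, semi_axes, rotation_deg = 0, n_vertices = 720) {
  a <- semi_axes[1L]; b <- semi_axes[2L]
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("ellipse semi-axes must both be positive", call. = FALSE)
  }
  th <- 2 * pi * seq(0L, n_vertices - 1L) / n_vertices
  rot <- rotation_deg * pi / 180
  x0 <- a * cos(th); y0 <- b * sin(th)
  poly_shape(cbind(center[1L] + cos(rot) * x0 - sin(rot) * y0,
                   center[2L] + sin(rot) * x0 + cos(rot) * y0),
             check = FALSE, orient = FALSE)
}

#' Triangle from three vertices
#'
#' @param vertices A 3x2 matrix (or list of three length-2 points). Must be
#'   non-collinear.
#' @return A `poly_shape` (counter-clockwise).
#' @export
triangle <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- matrix(as.numeric(vertices), ncol = 2L)
  if (nrow(vertices) != 3L) stop("a triangle needs exactly 3 vertices",
                                 call. = FALSE)
  ar <- ring_signed_area(vertices)
  if (abs(ar) < 1e-12) stop("triangle vertices are collinear", call. = FALSE)
  if (ar < 0) vertices <- vertices[3:1, , drop = FALSE]
  poly_shape(vertices, check = FALSE, orient = FALSE)
}

#' Rectangle with quarter-circle corners
#'
#' @param center Numeric length-2 center point.
#' @param width,height Side lengths, each strictly greater than
#'   `2 * corner_radius`.
#' @param corner_radius Non-negative corner radius; 0 gives a plain
#'   rectangle.
#' @param rotation_deg Rotation in degrees, counter-clockwise.
#' @param n_vertices Vertices per full turn used for the corner arcs.
#' @return A `poly_shape`.
#' @export
rounded_rectangle <- function(center, width, height, corner_radius = 0,
                              rotation_deg = 0, n_vertices = 720) {
  if (corner_radius < 0) stop("`corner_radius` must be non-negative",
                              call. = FALSE)
  if (width <= 2 * corner_radius || height <= 2 * corner_radius) {
    stop("`width` and `height` must both exceed 2 * corner_radius",
         call. = FALSE)
  }
  hw <- width / 2; hh <- height / 2; r <- corner_radius
  if (r == 0) {
    pts <- cbind(c(hw, hw, -hw, -hw), c(-hh, hh, hh, -hh))
  } else {
    n_arc <- max(2L, round(n_vertices / 4))
    qt <- seq(0, pi / 2, length.out = n_arc + 1L)
    corner <- function(cx, cy, t0) cbind(cx + r * cos(t0 + qt),
                                         cy + r * sin(t0 + qt))
    pts <- rbind(
      corner(hw - r, hh - r, 0),          # top-right
      corner(-hw + r, hh - r, pi / 2),    # top-left
      corner(-hw + r, -hh + r, pi),       # bottom-left
      corner(hw - r, -hh + r, 3 * pi / 2) # bottom-right
    )
  }
  rot <- rotation_deg * pi / 180
  poly_shape(cbind(center[1L] + cos(rot) * pts[, 1L] - sin(rot) * pts[, 2L],
                   center[2L] + sin(rot) * pts[, 1L] + cos(rot) * pts[, 2L]),
             check = FALSE, orient = FALSE)
}
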