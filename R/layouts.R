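# Shape layouts: one closed shape per set, a boundary polyline (edge) and a
# set-label anchor, for 2..7 sets. Built-in families:
#   * classic      — overlapping circles (n = 2, 3) and four congruent
#                    ellipses at +-45 degrees (n = 4),
#   * constructive — an Edwards-style construction valid for n = 3..7:
#                    two perpendicular half-plane slabs, a disc, and
#                    cogwheel (gear) discs whose boundary radius alternates
#                    r0 +- w with 2^(k-3) teeth for set k >= 4.
# All builtin layouts are deterministic and pass validate_layout().

#' Construct a shape layout
#'
#' @param shapes List of `poly_shape` objects, one per set, in set order.
#' @param set_label_anchors Optional list/matrix of per-set label anchor
#'   points; computed by the default placement rule (see [label_position()])
#'   when missing.
#' @param provenance One of `"builtin-classic"`, `"builtin-constructive"`,
#'   `"custom"`.
#' @return An object of class `shape_layout` with fields `n`, `shapes`,
#'   `edges` (closed boundary polylines), `set_label_anchors`, `provenance`.
#' @export
shape_layout <- function(shapes, set_label_anchors = NULL,
                         provenance = "custom") {
  if (!is.list(shapes) || !all(vapply(shapes, inherits, logical(1), "poly_shape"))) {
    stop("`shapes` must be a list of poly_shape objects", call. = FALSE)
  }
  n <- check_set_count(length(shapes))
  edges <- lapply(shapes, function(p) p$rings)
  user_anchor <- !is.null(set_label_anchors)
  layout <- structure(
    list(n = n, shapes = shapes, edges = edges,
         set_label_anchors = vector("list", n),
         provenance = provenance),
    class = "shape_layout", user_anchors = user_anchor)
  if (user_anchor) {
    if (is.matrix(set_label_anchors)) {
      set_label_anchors <- lapply(seq_len(nrow(set_label_anchors)),
                                  function(i) set_label_anchors[i, ])
    }
    if (length(set_label_anchors) != n) {
      stop("need one set label anchor per shape", call. = FALSE)
    }
    layout$set_label_anchors <- lapply(set_label_anchors, as.numeric)
  } else {
    layout$set_label_anchors <- lapply(seq_len(n), function(i)
      default_label_anchor(layout, i))
  }
  layout
}

#' @export
print.shape_layout <- function(x, ...) {
  cat("shape_layout:", x$n, "sets,", x$provenance, "\n")
  invisible(x)
}

check_layout <- function(layout) {
  if (!inherits(layout, "shape_layout")) {
    stop("expected a `shape_layout` object", call. = FALSE)
  }
  invisible(layout)
}

#' Default set-label anchor placement
#'
#' The default anchor for a set label sits just outside the shape, offset
#' outward from the boundary point farthest from the layout centroid. If the
#' layout was built with user-supplied anchors these pass through unchanged.
#'
#' @param layout A `shape_layout`.
#' @param set_index Set index in 1..n.
#' @return Numeric length-2 anchor point.
#' @export
label_position <- function(layout, set_index) {
  check_layout(layout)
  if (length(set_index) != 1L || is.na(set_index) ||
      set_index < 1L || set_index > layout$n) {
    stop("`set_index` must be in 1..", layout$n, call. = FALSE)
  }
  if (isTRUE(attr(layout, "user_anchors"))) {
    return(layout$set_label_anchors[[set_index]])
  }
  default_label_anchor(layout, set_index)
}

default_label_anchor <- function(layout, set_index, offset = 0.05) {
  ctr <- layout_centroid(layout)
  verts <- do.call(rbind, lapply(layout$shapes[[set_index]]$rings, ring_open))
  d2 <- (verts[, 1L] - ctr[1L])^2 + (verts[, 2L] - ctr[2L])^2
  far <- verts[which.max(d2), ]
  dir <- far - ctr
  len <- sqrt(sum(dir^2))
  if (len < 1e-12) dir <- c(0, 1) else dir <- dir / len
  as.numeric(far + offset * dir)
}

layout_centroid <- function(layout) {
  verts <- do.call(rbind, lapply(layout$shapes, function(p)
    do.call(rbind, lapply(p$rings, ring_open))))
  c(mean(verts[, 1L]), mean(verts[, 2L]))
}

#' Built-in Venn layouts for 2 to 7 sets
#'
#' `family = "classic"` gives overlapping circles (n = 2, 3) and four
#' congruent ellipses (n = 4); `family = "constructive"` gives the
#' Edwards-style construction (n = 3..7). The default `"auto"` picks classic
#' for n <= 4 and constructive above. All layouts are deterministic: the same
#' `n` always yields identical coordinates.
#'
#' @param n Number of sets, 2..7.
#' @param family `"auto"`, `"classic"` or `"constructive"`.
#' @return A `shape_layout` that passes [validate_layout()].
#' @export
#' @examples
#' builtin_layout(3)
builtin_layout <- function(n, family = c("auto", "classic", "constructive")) {
  n <- check_set_count(n)
  family <- match.arg(family)
  if (family == "auto") family <- if (n <= 4L) "classic" else "constructive"
  if (family == "classic") {
    if (n > 4L) {
      stop("the classic circle/ellipse family stops at 4 sets; use ",
           'family = "constructive" for n = 5..7', call. = FALSE)
    }
    switch(as.character(n),
           "2" = layout_two_circles(),
           "3" = layout_three_circles(),
           "4" = layout_four_ellipses())
  } else {
    if (n < 3L) {
      stop("the constructive family needs at least 3 sets; use the classic ",
           "circles for n = 2", call. = FALSE)
    }
    edwards_layout(n)
  }
}

layout_two_circles <- function() {
  shape_layout(
    list(circle(c(0.35, 0.5), 0.27),
         circle(c(0.65, 0.5), 0.27)),
    provenance = "builtin-classic")
}

layout_three_circles <- function() {
  ang <- c(90, 210, 330) * pi / 180
  d <- 0.14
  shapes <- lapply(ang, function(a)
    circle(c(0.5 + d * cos(a), 0.5 + d * sin(a)), 0.25))
  shape_layout(shapes, provenance = "builtin-classic")
}

# Four congruent ellipses (axis ratio 2:1) at +-45 degrees; parameters tuned
# once so that all 15 regions have positive area, then frozen.
CLASSIC4_PARAMS <- list(
  a = 0.32, b = 0.16,
  centers = rbind(c(0.35, 0.47), c(0.43, 0.57), c(0.57, 0.57), c(0.65, 0.47)),
  rotations = c(-45, -45, 45, 45))

layout_four_ellipses <- function() {
  p <- CLASSIC4_PARAMS
  shapes <- lapply(1:4, function(i)
    ellipse(p$centers[i, ], c(p$a, p$b), p$rotations[i]))
  shape_layout(shapes, provenance = "builtin-classic")
}

#' Edwards-style constructive Venn layout
#'
#' A construction that scales to any supported n: set 1 is the left
#' half-plane and set 2 the lower half-plane (both clipped to the drawing
#' frame), set 3 is a disc, and every further set k is a cogwheel (gear)
#' disc around the disc boundary whose radius alternates between `r0 - w_k`
#' and `r0 + w_k` with `2^(k-3)` teeth. Tooth phases are offset so each gear
#' splits every angular cell created by the previous sets, which guarantees
#' all `2^n - 1` regions exist.
#'
#' @param n Number of sets, 3..7.
#' @param r0 Disc radius (plot units, frame is the unit square).
#' @param widths Radial half-widths of the gear teeth for sets 4..7;
#'   strictly decreasing so the gear bands nest.
#' @return A `shape_layout` with provenance `"builtin-constructive"`.
#' @export
edwards_layout <- function(n, r0 = 0.28,
                           widths = c(0.10, 0.065, 0.042, 0.020)) {
  if (length(n) != 1L || is.na(n) || n != as.integer(n) || n < 3L || n > 7L) {
    stop("the Edwards-style construction supports n = 3..7", call. = FALSE)
  }
  n <- as.integer(n)
  ctr <- c(0.5, 0.5)
  shapes <- list(
    poly_shape(cbind(c(0.05, 0.5, 0.5, 0.05), c(0.05, 0.05, 0.95, 0.95)),
               check = FALSE, orient = FALSE),
    poly_shape(cbind(c(0.05, 0.95, 0.95, 0.05), c(0.05, 0.05, 0.5, 0.5)),
               check = FALSE, orient = FALSE),
    circle(ctr, r0))
  if (n >= 4L) {
    for (k in 4:n) {
      teeth <- 2L^(k - 3L)
      shapes[[k]] <- gear_shape(ctr, r0, widths[k - 3L], teeth,
                                phase = pi / (2L * teeth))
    }
  }
  # gears share their farthest-point direction, so the default outward rule
  # would stack their labels; use fixed well-separated anchors instead
  r_lab <- r0 + max(widths) + 0.08
  gear_ang <- c(45, 315, 225, 90) * pi / 180
  anchors <- c(list(c(0.10, 0.93), c(0.90, 0.07),
                    ctr + (r0 + 0.12) * c(cos(3 * pi / 4), sin(3 * pi / 4))),
               lapply(gear_ang, function(a) ctr + r_lab * c(cos(a), sin(a))))
  shape_layout(shapes[seq_len(n)], set_label_anchors = anchors[seq_len(n)],
               provenance = "builtin-constructive")
}

# Gear (cogwheel) disc: star-shaped region whose boundary radius alternates
# between r0 - w (valleys) and r0 + w (teeth); `teeth` tooth arcs per turn,
# first tooth starting at angle `phase`. Arc resolution follows the package
# default of 720 vertices per full turn.
gear_shape <- function(center, r0, w, teeth, phase, pts_per_turn = 720) {
  half <- pi / teeth                    # angular width of one tooth / valley
  trans <- phase + half * seq(0L, 2L * teeth - 1L)  # state-change angles
  verts <- list()
  for (s in seq_along(trans)) {
    a0 <- trans[s]
    a1 <- trans[s] + half
    r <- if (s %% 2L == 1L) r0 + w else r0 - w     # tooth first
    m <- max(3L, ceiling((a1 - a0) / (2 * pi) * pts_per_turn))
    th <- seq(a0, a1, length.out = m + 1L)[-(m + 1L)]
    verts[[s]] <- cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
  }
  poly_shape(do.call(rbind, verts), check = FALSE, orient = FALSE)
}

#' Four-set layout from rounded rectangles
#'
#' The classic four-ellipse arrangement realised with four congruent rounded
#' rectangles (aspect 2:1, +-45 degree rotations); an example of composing a
#' complete Venn layout from a non-elliptical primitive.
#'
#' @return A `shape_layout` with 4 sets that passes [validate_layout()].
#' @export
layout_rounded_rectangles <- function() {
  p <- CLASSIC4_PARAMS
  shapes <- lapply(1:4, function(i)
    rounded_rectangle(p$centers[i, ], width = 2 * p$a, height = 2 * p$b,
                      corner_radius = p$b / 2, rotation_deg = p$rotations[i]))
  shape_layout(shapes, provenance = "builtin-classic")
}

#' Six-set layout from six triangles
#'
#' Reads the packaged six-triangle coordinate fixture (shapes CSV) and
#' composes the layout through the [triangle()] primitive: a complete 6-set
#' Venn diagram made of exactly six triangles.
#'
#' @return A `shape_layout` with 6 sets.
#' @export
layout_six_triangles <- function() {
  path <- system.file("extdata", "six_triangles.csv", package = "vennkit",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  shapes <- lapply(split(df, df$shape_id), function(d)
    triangle(cbind(d$x, d$y)))
  shape_layout(shapes[order(as.integer(names(shapes)))],
               provenance = "builtin-classic")
}

# -- shapes CSV interchange ------------------------------------------------

#' Read and write layouts as shapes CSV
#'
#' The plain-text interchange format for custom layouts: a CSV with columns
#' `shape_id`, `ring_id`, `x`, `y`, one row per vertex, vertices of each ring
#' in drawing order. `shape_id` order defines set order.
#'
#' @param path File path.
#' @return `read_shape_csv()` returns a `shape_layout` with provenance
#'   `"custom"`.
#' @export
read_shape_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("shape_id", "ring_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("shapes CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sids <- unique(df$shape_id)
  shapes <- lapply(sids, function(s) {
    d <- df[df$shape_id == s, , drop = FALSE]
    rings <- lapply(split(d, d$ring_id), function(rr) cbind(rr$x, rr$y))
    poly_shape(rings)
  })
  shape_layout(shapes, provenance = "custom")
}

#' @rdname read_shape_csv
#' @param layout A `shape_layout`.
#' @export
write_shape_csv <- function(layout, path) {
  check_layout(layout)
  rows <- list()
  for (i in seq_len(layout$n)) {
    for (j in seq_along(layout$shapes[[i]]$rings)) {
      r <- ring_open(layout$shapes[[i]]$rings[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        shape_id = i, ring_id = j, x = r[, 1L], y = r[, 2L])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
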