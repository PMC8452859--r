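# Rendering: build a figure from plot data + style, draw it on R graphics
# devices (PNG/PDF and interactive) and write deterministic SVG.
#
# The figure is drawn in four layers, bottom to top:
#   1 region polygons filled by a gradient mapped to count (or percent),
#     with a color-bar legend
#   2 set edge outlines
#   3 set labels at their anchors
#   4 region labels (count/percent) at region anchors; zero-area regions
#     have no geometry and therefore no label (their counts still appear in
#     the region table)

#' Render a Venn figure
#'
#' @param pd A `venn_plot_data` with attached values (see
#'   [build_plot_data()]).
#' @param style A `venn_style`.
#' @return An object of class `venn_figure`; `print()`/`plot()` draws it on
#'   the current device, [export()] writes SVG/PNG/PDF.
#' @export
#' @examples
#' v <- make_venn(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' fig <- render(build_plot_data(v, builtin_layout(2)), venn_style())
render <- function(pd, style = venn_style()) {
  check_plot_data(pd)
  check_style(style)
  if (anyNA(pd$regions$count)) {
    stop("plot data has no attached values; call attach_sets() first",
         call. = FALSE)
  }
  # resolve per-set edge colors now so bad set names fail early
  resolve_edge_colors(style$edge_color, pd$set_edges$name)
  structure(list(pd = pd, style = style), class = "venn_figure")
}

#' One-call Venn diagram
#'
#' Convenience wrapper: builds the collection, picks the default layout for
#' its size, joins, and renders with default style. Satisfactory figures
#' need nothing beyond the input sets.
#'
#' @param sets A named list of character vectors (2..7 sets) or a `venn`.
#' @param layout Optional `shape_layout`; defaults to [builtin_layout()]
#'   for the collection size.
#' @param style A `venn_style`.
#' @return A `venn_figure`.
#' @export
venn_plot <- function(sets, layout = NULL, style = venn_style()) {
  venn <- if (inherits(sets, "venn")) sets else make_venn(sets)
  if (is.null(layout)) layout <- builtin_layout(venn$n)
  render(build_plot_data(venn, layout), style)
}

resolve_edge_colors <- function(edge_color, set_names) {
  if (!is.null(names(edge_color)) && any(nzchar(names(edge_color)))) {
    unknown <- setdiff(names(edge_color), set_names)
    if (length(unknown)) {
      stop("edge_color refers to unknown set name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- rep(edge_color[1L], length(set_names))
    hit <- match(set_names, names(edge_color))
    out[!is.na(hit)] <- edge_color[hit[!is.na(hit)]]
    unname(out)
  } else {
    rep_len(unname(edge_color), length(set_names))
  }
}

# -- scene: everything the writers need, resolved once ---------------------

build_scene <- function(fig) {
  pd <- fig$pd
  style <- fig$style
  rg <- pd$regions
  drawn <- !vapply(rg$poly, poly_is_empty, logical(1))

  fill_vals <- switch(style$fill_by,
                      count = rg$count, percent = rg$percent, none = NULL)
  if (is.null(fill_vals)) {
    fills <- rep("#D9D9D9", nrow(rg))
    legend_range <- NULL
    pos <- rep(NA_real_, nrow(rg))
  } else {
    vmin <- min(fill_vals); vmax <- max(fill_vals)
    pos <- if (vmax > vmin) (fill_vals - vmin) / (vmax - vmin)
           else rep(0.5, length(fill_vals))
    fills <- colormap_ramp(style$colormap)(pos)
    legend_range <- c(vmin, vmax)
  }

  # data window: shapes plus label anchors, padded
  pts <- do.call(rbind, c(
    lapply(pd$set_edges$edge, function(rs) do.call(rbind, lapply(rs, ring_open))),
    lapply(pd$set_edges$label_anchor, function(a) matrix(a, ncol = 2L))))
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  padx <- 0.06 * diff(xr); pady <- 0.06 * diff(yr)
  window <- c(xr[1L] - padx, yr[1L] - pady, xr[2L] + padx, yr[2L] + pady)

  set_label_text <- switch(style$set_label,
    "name" = pd$set_edges$name,
    "name+size" = sprintf("%s (%d)", pd$set_edges$name, pd$set_edges$set_size),
    "none" = NULL)
  region_label_text <- switch(style$region_label,
    "count" = sprintf("%d", rg$count),
    "percent" = sprintf("%.1f%%", rg$percent),
    "both" = sprintf("%d (%.1f%%)", rg$count, rg$percent),
    "none" = NULL)

  list(
    window = window,
    regions = rg[drawn, , drop = FALSE],
    region_fills = fills[drawn],
    region_labels = if (!is.null(region_label_text)) region_label_text[drawn],
    edges = pd$set_edges$edge,
    edge_colors = resolve_edge_colors(style$edge_color, pd$set_edges$name),
    set_names = pd$set_edges$name,
    set_anchors = pd$set_edges$label_anchor,
    set_labels = set_label_text,
    legend_range = if (style$legend && style$layers[1L]) legend_range,
    legend_title = style$fill_by,
    style = style)
}

#' Export a figure to SVG, PNG or PDF
#'
#' SVG output is written by vennkit itself and is byte-deterministic:
#' rendering the same plot data and style twice yields identical files (no
#' timestamps or environment metadata). PNG and PDF go through the
#' corresponding `grDevices` devices.
#'
#' @param fig A `venn_figure`.
#' @param path Output file path.
#' @param format `"svg"`, `"png"` or `"pdf"`; defaults to the file
#'   extension.
#' @param dpi Resolution for PNG output; the raster is
#'   `width * dpi` by `height * dpi` pixels.
#' @return `path`, invisibly.
#' @export
export <- function(fig, path, format = NULL, dpi = 150) {
  if (!inherits(fig, "venn_figure")) {
    stop("expected a `venn_figure` (see render())", call. = FALSE)
  }
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!nzchar(format)) format <- "svg"
  }
  if (!format %in% c("svg", "png", "pdf")) {
    stop("unknown format '", format, "' (supported: svg, png, pdf)",
         call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write to '", path, "': directory does not exist",
         call. = FALSE)
  }
  st <- fig$style
  if (format == "svg") {
    writeLines(svg_document(fig), path, useBytes = TRUE)
  } else if (format == "png") {
    grDevices::png(path, width = st$width * dpi, height = st$height * dpi,
                   res = dpi, bg = st$background)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_figure(fig)
  } else {
    grDevices::pdf(path, width = st$width, height = st$height,
                   bg = st$background)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_figure(fig)
  }
  invisible(path)
}

#' @export
print.venn_figure <- function(x, ...) {
  draw_figure(x)
  invisible(x)
}

#' @export
plot.venn_figure <- function(x, ...) {
  draw_figure(x)
  invisible(x)
}

# -- base-graphics drawing (PNG/PDF/interactive) ---------------------------

draw_figure <- function(fig) {
  sc <- build_scene(fig)
  st <- sc$style
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, if (!is.null(sc$legend_range)) 6 else 0.5))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = sc$window[c(1L, 3L)],
                        ylim = sc$window[c(2L, 4L)], asp = 1)
  if (st$layers[1L]) {
    for (i in seq_len(nrow(sc$regions))) {
      p <- sc$regions$poly[[i]]
      xs <- ys <- numeric(0)
      for (r in p$rings) {
        ro <- ring_open(r)
        xs <- c(xs, NA, ro[, 1L]); ys <- c(ys, NA, ro[, 2L])
      }
      graphics::polypath(xs[-1L], ys[-1L], rule = "evenodd",
                         col = sc$region_fills[i], border = NA)
    }
  }
  if (st$layers[2L]) {
    for (i in seq_along(sc$edges)) {
      for (r in sc$edges[[i]]) {
        graphics::lines(r[, 1L], r[, 2L], col = sc$edge_colors[i],
                        lwd = st$edge_width, lty = st$edge_linetype)
      }
    }
  }
  if (st$layers[3L] && !is.null(sc$set_labels)) {
    for (i in seq_along(sc$set_labels)) {
      a <- sc$set_anchors[[i]]
      graphics::text(a[1L], a[2L], sc$set_labels[i], cex = st$set_label_size)
    }
  }
  if (st$layers[4L] && !is.null(sc$region_labels)) {
    for (i in seq_len(nrow(sc$regions))) {
      a <- sc$regions$label_anchor[[i]]
      if (is.null(a)) next
      graphics::text(a[1L], a[2L], sc$region_labels[i],
                     cex = st$region_label_size)
    }
  }
  if (!is.null(sc$legend_range)) {
    draw_device_legend(sc)
  }
  invisible(NULL)
}

draw_device_legend <- function(sc) {
  usr <- graphics::par("usr")
  ramp <- colormap_ramp(sc$style$colormap)
  x0 <- usr[2L] + 0.02 * (usr[2L] - usr[1L])
  w <- 0.04 * (usr[2L] - usr[1L])
  y0 <- usr[3L] + 0.25 * (usr[4L] - usr[3L])
  y1 <- usr[4L] - 0.25 * (usr[4L] - usr[3L])
  nb <- 64L
  ys <- seq(y0, y1, length.out = nb + 1L)
  old <- graphics::par(xpd = NA)
  on.exit(graphics::par(old), add = TRUE)
  for (b in seq_len(nb)) {
    graphics::rect(x0, ys[b], x0 + w, ys[b + 1L],
                   col = ramp((b - 0.5) / nb), border = NA)
  }
  graphics::rect(x0, y0, x0 + w, y1, border = "grey30", lwd = 0.5)
  lr <- sc$legend_range
  graphics::text(x0 + w * 1.4, y0, format_legend_value(lr[1L]), adj = 0, cex = 0.8)
  graphics::text(x0 + w * 1.4, y1, format_legend_value(lr[2L]), adj = 0, cex = 0.8)
  graphics::text(x0 + w / 2, y1 + 0.05 * (usr[4L] - usr[3L]),
                 sc$legend_title, cex = 0.9)
}

format_legend_value <- function(v) {
  if (v == round(v)) sprintf("%d", as.integer(round(v))) else sprintf("%.1f", v)
}
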