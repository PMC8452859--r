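# Deterministic SVG 1.1 writer. Identical plot data + style always produce
# byte-identical output: fixed coordinate formatting, no timestamps, no
# library version strings. Element ids are stable and census-friendly:
#   region-<mask>        filled region paths          (layer 1)
#   edge-<set name>      set boundary outlines        (layer 2)
#   setlabel-<set name>  set label text               (layer 3)
#   regionlabel-<mask>   region label text            (layer 4)

svg_document <- function(fig) {
  sc <- build_scene(fig)
  st <- sc$style
  wpx <- round(96 * st$width)
  hpx <- round(96 * st$height)
  legend_pad <- if (!is.null(sc$legend_range)) 90 else 0
  win <- sc$window
  sx <- (wpx - 20 - legend_pad) / (win[3L] - win[1L])
  sy <- (hpx - 20) / (win[4L] - win[2L])
  s <- min(sx, sy)
  tx <- function(x) sprintf("%.3f", 10 + (x - win[1L]) * s)
  ty <- function(y) sprintf("%.3f", hpx - 10 - (y - win[2L]) * s)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
            wpx, hpx, wpx, hpx),
    sprintf('<rect id="background" width="%d" height="%d" fill="%s"/>',
            wpx, hpx, col_to_hex(st$background)))

  path_d <- function(p) {
    paste(vapply(p$rings, function(r) {
      ro <- ring_open(r)
      paste0("M", tx(ro[1L, 1L]), ",", ty(ro[1L, 2L]), " L",
             paste(tx(ro[-1L, 1L]), ty(ro[-1L, 2L]), sep = ",",
                   collapse = " "), " Z")
    }, character(1)), collapse = " ")
  }

  if (st$layers[1L]) {
    out <- c(out, '<g id="layer-fills">')
    for (i in seq_len(nrow(sc$regions))) {
      out <- c(out, sprintf(
        '<path id="region-%s" d="%s" fill="%s" fill-rule="evenodd" stroke="none"/>',
        sc$regions$mask[i], path_d(sc$regions$poly[[i]]),
        col_to_hex(sc$region_fills[i])))
    }
    out <- c(out, '</g>')
  }
  if (st$layers[2L]) {
    out <- c(out, '<g id="layer-edges">')
    for (i in seq_along(sc$edges)) {
      d <- path_d(new_poly(sc$edges[[i]]))
      out <- c(out, sprintf(
        '<path id="edge-%s" d="%s" fill="none" stroke="%s" stroke-width="%.2f"%s/>',
        xml_escape(sc$set_names[i]), d, col_to_hex(sc$edge_colors[i]),
        st$edge_width, svg_dash(st$edge_linetype)))
    }
    out <- c(out, '</g>')
  }
  if (st$layers[3L] && !is.null(sc$set_labels)) {
    out <- c(out, '<g id="layer-set-labels">')
    for (i in seq_along(sc$set_labels)) {
      a <- sc$set_anchors[[i]]
      out <- c(out, sprintf(
        '<text id="setlabel-%s" x="%s" y="%s" text-anchor="middle" font-family="sans-serif" font-size="%.1f">%s</text>',
        xml_escape(sc$set_names[i]), tx(a[1L]), ty(a[2L]),
        12 * st$set_label_size, xml_escape(sc$set_labels[i])))
    }
    out <- c(out, '</g>')
  }
  if (st$layers[4L] && !is.null(sc$region_labels)) {
    out <- c(out, '<g id="layer-region-labels">')
    for (i in seq_len(nrow(sc$regions))) {
      a <- sc$regions$label_anchor[[i]]
      if (is.null(a)) next
      out <- c(out, sprintf(
        '<text id="regionlabel-%s" x="%s" y="%s" text-anchor="middle" font-family="sans-serif" font-size="%.1f">%s</text>',
        sc$regions$mask[i], tx(a[1L]), ty(a[2L]),
        11 * st$region_label_size, xml_escape(sc$region_labels[i])))
    }
    out <- c(out, '</g>')
  }
  if (!is.null(sc$legend_range)) {
    out <- c(out, svg_legend(sc, wpx, hpx, legend_pad))
  }
  c(out, '</svg>')
}

svg_legend <- function(sc, wpx, hpx, legend_pad) {
  ramp <- colormap_ramp(sc$style$colormap)
  x0 <- wpx - legend_pad + 20
  bw <- 16
  y1 <- round(hpx * 0.28)
  y0 <- round(hpx * 0.72)
  stops <- vapply(0:32, function(k) {
    sprintf('<stop offset="%.4f" stop-color="%s"/>', k / 32, ramp(k / 32))
  }, character(1))
  lr <- sc$legend_range
  c('<g id="legend">',
    '<defs><linearGradient id="legend-gradient" x1="0" y1="1" x2="0" y2="0">',
    stops,
    '</linearGradient></defs>',
    sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="url(#legend-gradient)" stroke="#4d4d4d" stroke-width="0.5"/>',
            x0, y1, bw, y0 - y1),
    sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="10">%s</text>',
            x0 + bw + 6, y0 + 4, xml_escape(format_legend_value(lr[1L]))),
    sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="10">%s</text>',
            x0 + bw + 6, y1 + 4, xml_escape(format_legend_value(lr[2L]))),
    sprintf('<text x="%d" y="%d" font-family="sans-serif" font-size="11">%s</text>',
            x0, y1 - 10, xml_escape(sc$legend_title)),
    '</g>')
}

svg_dash <- function(lty) {
  if (is.numeric(lty) && lty == 1) return("")
  pat <- switch(as.character(lty),
                "2" = "6,4", "3" = "2,3", "4" = "2,3,6,3",
                "5" = "10,4", "6" = "6,3,2,3", "")
  if (nzchar(pat)) sprintf(' stroke-dasharray="%s"', pat) else ""
}

col_to_hex <- function(col) {
  m <- grDevices::col2rgb(col)
  sprintf("#%02X%02X%02X", m[1L], m[2L], m[3L])
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}
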