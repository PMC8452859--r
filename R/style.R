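# Style configuration for the four render layers:
#   1 region fills (gradient mapped to count/percent, with legend)
#   2 set edges
#   3 set labels
#   4 region labels

STYLE_FIELDS <- c("colormap", "fill_by", "edge_color", "edge_width",
                  "edge_linetype", "set_label", "region_label", "legend",
                  "width", "height", "background", "set_label_size",
                  "region_label_size", "layers")

#' Style configuration for Venn figures
#'
#' @param colormap Name of a continuous `viridisLite` map (`"viridis"`,
#'   `"magma"`, `"plasma"`, `"inferno"`, `"cividis"`, `"mako"`, `"rocket"`,
#'   `"turbo"`), or a character vector of colors to interpolate. The default
#'   viridis map runs dark blue to yellow and is perceptually uniform.
#' @param fill_by What the region fill gradient encodes: `"count"`,
#'   `"percent"` or `"none"` (flat fill, no legend).
#' @param edge_color A single color, or a named vector of colors keyed by
#'   set name.
#' @param edge_width Edge line width (device line-width units).
#' @param edge_linetype Line type for set edges (as `lty`).
#' @param set_label `"name"`, `"name+size"` or `"none"`.
#' @param region_label `"count"`, `"percent"`, `"both"` or `"none"`.
#' @param legend Show the color-bar legend for the fill gradient?
#' @param width,height Figure size in inches.
#' @param background Background color.
#' @param set_label_size,region_label_size Text sizes (cex units, relative
#'   to the figure; never below 0.5 so labels stay readable).
#' @param layers Logical vector of length 4 toggling the four layers
#'   (fills, edges, set labels, region labels).
#' @return An object of class `venn_style`.
#' @export
#' @examples
#' venn_style(fill_by = "percent", legend = FALSE)
venn_style <- function(colormap = "viridis",
                       fill_by = c("count", "percent", "none"),
                       edge_color = "grey20",
                       edge_width = 1.2,
                       edge_linetype = 1,
                       set_label = c("name+size", "name", "none"),
                       region_label = c("count", "percent", "both", "none"),
                       legend = TRUE,
                       width = 7, height = 7,
                       background = "white",
                       set_label_size = 1.1,
                       region_label_size = 0.9,
                       layers = c(TRUE, TRUE, TRUE, TRUE)) {
  fill_by <- match.arg(fill_by)
  set_label <- match.arg(set_label)
  region_label <- match.arg(region_label)
  if (!is.logical(layers) || length(layers) != 4L || anyNA(layers)) {
    stop("`layers` must be 4 logical values (fills, edges, set labels, ",
         "region labels)", call. = FALSE)
  }
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    stop("`width` and `height` must be positive", call. = FALSE)
  }
  structure(list(
    colormap = colormap, fill_by = fill_by, edge_color = edge_color,
    edge_width = edge_width, edge_linetype = edge_linetype,
    set_label = set_label, region_label = region_label,
    legend = isTRUE(legend), width = width, height = height,
    background = background,
    set_label_size = max(0.5, set_label_size),
    region_label_size = max(0.5, region_label_size),
    layers = layers), class = "venn_style")
}

check_style <- function(style) {
  if (!inherits(style, "venn_style")) {
    stop("expected a `venn_style` object (see venn_style())", call. = FALSE)
  }
  invisible(style)
}

#' Build a style from a YAML/list configuration
#'
#' Option names mirror the arguments of [venn_style()]; unknown option names
#' are rejected at parse time.
#'
#' @param config A file path to a YAML file, or a named list.
#' @return A `venn_style`.
#' @export
style_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML file path",
                             call. = FALSE)
  unknown <- setdiff(names(config), STYLE_FIELDS)
  if (length(unknown)) {
    stop("unknown style option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(venn_style, config)
}

#' Toggle one of the four render layers
#'
#' Layers: 1 region fills, 2 set edges, 3 set labels, 4 region labels.
#' Toggling the same layer twice restores the original style.
#'
#' @param style A `venn_style`.
#' @param layer Integer 1..4.
#' @param on Logical.
#' @return The modified `venn_style`.
#' @export
#' @examples
#' edges_only <- layer_toggle(layer_toggle(layer_toggle(
#'   venn_style(), 1, FALSE), 3, FALSE), 4, FALSE)
layer_toggle <- function(style, layer, on) {
  check_style(style)
  if (length(layer) != 1L || is.na(layer) || !(layer %in% 1:4)) {
    stop("`layer` must be 1 (fills), 2 (edges), 3 (set labels) or ",
         "4 (region labels)", call. = FALSE)
  }
  style$layers[layer] <- isTRUE(on)
  style
}

# resolve the colormap to a color ramp function position -> hex color
colormap_ramp <- function(colormap) {
  pal <- if (is.character(colormap) && length(colormap) == 1L &&
             colormap %in% c("viridis", "magma", "plasma", "inferno",
                             "cividis", "mako", "rocket", "turbo")) {
    viridisLite::viridis(256L, option = colormap)
  } else if (is.character(colormap) && length(colormap) >= 2L) {
    grDevices::colorRampPalette(colormap)(256L)
  } else {
    stop("`colormap` must name a viridisLite map or give >= 2 colors",
         call. = FALSE)
  }
  pal <- substr(pal, 1L, 7L)  # strip alpha, keep #rrggbb
  function(pos) pal[pmin(256L, pmax(1L, floor(pos * 255) + 1L))]
}
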