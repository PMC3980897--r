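#' Rendering configuration
#'
#' All geometric and color defaults of the two views, overridable per call
#' or from a YAML/JSON config file. Lengths are in pixels.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `enroute_config`.
#'
#' @details Defaults:
#' \describe{
#'   \item{row_height (18)}{uniform height of one data row in the linear view.}
#'   \item{min_node_height (30)}{minimum vertical extent of a path node block.}
#'   \item{node_gap (12)}{vertical gap between consecutive node blocks.}
#'   \item{bar_width (6)}{width per sample bar in detailed columns.}
#'   \item{abstract_width (64)}{fixed width of abstract group columns.}
#'   \item{column_gap (10)}{horizontal gap between group columns.}
#'   \item{binary_rows (3)}{row count of the mutation-status matrix, filled
#'     column-major.}
#'   \item{radius (12)}{corridor half-width around the path.}
#'   \item{margin (6)}{clearance kept from off-path node boxes.}
#'   \item{t_low, t_high (0.3, 1.0)}{thresholds of [categorize_cnv()] on a
#'     log2-ratio-like scale.}
#'   \item{shades ("#F0F0F0", "#E1E1E1")}{alternating per-node background
#'     grays of the data rows.}
#'   \item{diverging (blue/white/red)}{low/mid/high colors of the on-node
#'     color map.}
#'   \item{cnv_colors}{dark blue, light blue, light red, dark red for the
#'     four non-normal copy-number categories.}
#'   \item{mutation_color / no_mutation_color}{matrix cell fills.}
#'   \item{corridor_colors}{fills cycling over path alternatives; the first
#'     (orange) is the selected path.}
#' }
#' @export
enroute_config <- function(...) {
  cfg <- list(
    row_height = 18, min_node_height = 30, node_gap = 12,
    bar_width = 6, abstract_width = 64, column_gap = 10,
    binary_rows = 3,
    radius = 12, margin = 6,
    t_low = 0.3, t_high = 1.0,
    shades = c("#F0F0F0", "#E1E1E1"),
    diverging = list(low = "#2166AC", mid = "#FFFFFF", high = "#B2182B"),
    binary_map = list(low = "#CCCCCC", high = "#CB181D"),
    cnv_colors = c(hom_del = "#2166AC", het_del = "#92C5DE",
                   normal = "#FFFFFF", low_gain = "#F4A582",
                   high_gain = "#B2182B"),
    mutation_color = "#CB181D", no_mutation_color = "#D9D9D9",
    variance_bar_color = "#33A02C",
    missing_marker_color = "#555555",
    corridor_colors = c("#F28E2B", "#76B7B2", "#EDC948", "#B07AA1",
                        "#59A14F", "#9C755F"),
    forced_edge_color = "#E15759",
    ribbon_color = "#B0B0B0", ribbon_opacity = 0.45,
    highlight_color = "#FFD700",
    branch_slot_width = 90,
    font_family = "sans-serif", font_size = 10,
    caption_height = 16
  )
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && is.null(names(dots)))
    dots <- dots[[1]]
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "enroute_config")
}

#' Read a rendering/run configuration file
#' @param file YAML (or JSON) file of overrides.
#' @return An `enroute_config`.
#' @export
read_config <- function(file) {
  enroute_config(yaml::read_yaml(file))
}

#' Diverging color scale specification
#'
#' @param low,mid,high Hex colors (blue-white-red by default).
#' @param vmin,vmid,vmax Anchor values; `vmid` maps exactly to `mid`.
#' @return A list of class `diverging_spec`.
#' @export
diverging_spec <- function(low = "#2166AC", mid = "#FFFFFF", high = "#B2182B",
                           vmin = -1, vmid = 0, vmax = 1) {
  if (!(vmin < vmid && vmid < vmax)) stop("need vmin < vmid < vmax")
  structure(list(low = low, mid = mid, high = high,
                 vmin = vmin, vmid = vmid, vmax = vmax),
            class = "diverging_spec")
}

hex_to_rgb <- function(hex) {
  hex <- sub("^#", "", hex)
  c(strtoi(substr(hex, 1, 2), 16L), strtoi(substr(hex, 3, 4), 16L),
    strtoi(substr(hex, 5, 6), 16L))
}

rgb_to_hex <- function(rgb) {
  sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])
}

#' Map a value through a diverging color scale
#'
#' Piecewise-linear interpolation in RGB between the low and mid colors
#' below `vmid` and between mid and high above it; values are clamped to
#' `[vmin, vmax]`, so `vmid` maps exactly to the neutral mid color and the
#' extremes to the end colors.
#'
#' @param value Numeric vector (finite).
#' @param spec A [diverging_spec()].
#' @return Character vector of `#RRGGBB` colors.
#' @export
diverging_color <- function(value, spec) {
  vapply(value, function(v) {
    v <- min(max(v, spec$vmin), spec$vmax)
    if (v <= spec$vmid) {
      t <- if (spec$vmid == spec$vmin) 0 else (v - spec$vmin) / (spec$vmid - spec$vmin)
      a <- hex_to_rgb(spec$low); b <- hex_to_rgb(spec$mid)
    } else {
      t <- (v - spec$vmid) / (spec$vmax - spec$vmid)
      a <- hex_to_rgb(spec$mid); b <- hex_to_rgb(spec$high)
    }
    rgb_to_hex(as.integer(round(a + t * (b - a))))
  }, character(1))
}
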