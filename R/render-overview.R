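#' Render the annotated pathway overview as SVG
#'
#' Draws every node of the pathway at its original position. When a dataset
#' is supplied, nodes are filled by the mean of all mapped values through
#' the blue-white-red diverging map (gray-to-red for binary mutation
#' data), a green bar along the bottom edge encodes the standard deviation
#' relative to the largest standard deviation on the map, and a small
#' lower-left marker flags nodes with missing or unmapped data. A selected
#' path (or a whole set of alternatives, each in its own color with the
#' selected one emphasized) is wrapped in its corridor highlight with node
#' interiors cut out; forced edges are drawn dashed.
#'
#' @param graph A [pathway_graph()].
#' @param dataset Optional [omics_dataset()] to map on nodes.
#' @param grouping Optional [sample_grouping()]; with `group`, restricts
#'   the mapped samples to one group.
#' @param selection A [selected_path()], a `path_alternatives` object, or
#'   `NULL`.
#' @param config An [enroute_config()].
#' @param alias_table Optional alias translation for row matching.
#' @param group Optional group label (see `grouping`).
#' @return SVG document as a character string.
#' @export
render_overview <- function(graph, dataset = NULL, grouping = NULL,
                            selection = NULL, config = enroute_config(),
                            alias_table = NULL, group = NULL) {
  if (!is.null(group) && is.null(grouping))
    stop("grouping required when group is given")
  if (!is.null(dataset) && !is.null(grouping) &&
      !identical(grouping$dataset_id, dataset$dataset_id))
    stop("grouping refers to dataset '", grouping$dataset_id,
         "', not '", dataset$dataset_id, "'")

  parts <- character()

  # base topology
  e <- graph$edges
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    p <- graph$nodes[[e$source[i]]]$bbox; q <- graph$nodes[[e$target[i]]]$bbox
    parts <- c(parts, svg_line(p[1], p[2], q[1], q[2], class = "base-edge",
                               stroke = "#999999", `stroke-width` = 1))
  }

  # path corridor(s)
  sel_paths <- list()
  if (inherits(selection, "selected_path")) {
    sel_paths <- list(selection); sel_idx <- 1L
  } else if (inherits(selection, "path_alternatives")) {
    sel_paths <- selection$paths; sel_idx <- selection$selected
  }
  if (length(sel_paths)) {
    draw_order <- c(setdiff(seq_along(sel_paths), sel_idx), sel_idx)
    for (i in draw_order) {
      geom <- corridor(graph, sel_paths[[i]], config$radius, config$margin)
      col <- config$corridor_colors[(i - 1) %% length(config$corridor_colors) + 1]
      parts <- c(parts, svg_tag("path", list(
        d = svg_path_from_rings(c(geom$outline, geom$holes)),
        class = if (i == sel_idx) "corridor corridor-selected" else "corridor",
        fill = col, `fill-rule` = "evenodd",
        `fill-opacity` = if (i == sel_idx) 0.65 else 0.3)))
      fe <- sel_paths[[i]]$forced_edges
      if (nrow(fe)) for (k in seq_len(nrow(fe))) {
        p <- graph$nodes[[fe[k, 1]]]$bbox; q <- graph$nodes[[fe[k, 2]]]$bbox
        parts <- c(parts, svg_line(p[1], p[2], q[1], q[2], class = "forced-edge",
                                   stroke = config$forced_edge_color,
                                   `stroke-width` = 2,
                                   `stroke-dasharray` = "6,3"))
      }
    }
  }

  # node glyphs with on-node mapping
  summaries <- NULL
  spec <- NULL
  if (!is.null(dataset)) {
    summaries <- lapply(graph$nodes, node_summary, dataset = dataset,
                        grouping = grouping, group = group,
                        alias_table = alias_table, graph = graph)
    means <- vapply(summaries, function(s) if (s$defined) s$mean else NA_real_,
                    numeric(1))
    stds <- vapply(summaries, function(s) if (s$defined) s$std else 0, numeric(1))
    std_max <- max(stds, 1e-12)
    spec <- overview_scale(dataset$dtype, means, config)
  }
  for (n in graph$nodes) {
    r <- node_rect(n)
    fill <- "#FFFFFF"
    if (!is.null(summaries)) {
      s <- summaries[[n$node_id]]
      if (s$defined) fill <- diverging_color(s$mean, spec)
    }
    parts <- c(parts, svg_rect(r[1], r[2], r[3] - r[1], r[4] - r[2],
                               class = paste0("node-rect node-", n$kind),
                               id = paste0("node-", n$node_id),
                               fill = fill, stroke = "#000000",
                               `stroke-width` = 1))
    parts <- c(parts, svg_text(n$bbox[1], n$bbox[2] + config$font_size / 3,
                               n$label, class = "node-label",
                               `text-anchor` = "middle",
                               `font-family` = config$font_family,
                               `font-size` = config$font_size))
    if (!is.null(summaries)) {
      s <- summaries[[n$node_id]]
      if (s$defined && s$std > 0)
        parts <- c(parts, svg_rect(r[1], r[4] + 1,
                                   (r[3] - r[1]) * s$std / std_max, 3,
                                   class = "variance-bar",
                                   fill = config$variance_bar_color))
      if (s$has_missing)
        parts <- c(parts, svg_rect(r[1], r[4] - 4, 4, 4,
                                   class = "missing-marker",
                                   fill = config$missing_marker_color))
    }
  }
  svg_document(graph$image_size[1], graph$image_size[2] + 6, parts)
}

# value scale for on-node fills: symmetric around 0 for numerical data,
# the -2..2 code range for ordinal copy number, gray-to-red over [0, 1]
# for binary mutation fractions
overview_scale <- function(dtype, means, config) {
  d <- config$diverging
  switch(dtype,
    numerical = {
      m <- max(abs(means), na.rm = TRUE)
      if (!is.finite(m) || m == 0) m <- 1
      diverging_spec(d$low, d$mid, d$high, -m, 0, m)
    },
    ordinal_cnv = diverging_spec(d$low, d$mid, d$high, -2, 0, 2),
    binary = diverging_spec(config$binary_map$low,
                            mid_hex(config$binary_map$low, config$binary_map$high),
                            config$binary_map$high, 0, 0.5, 1))
}

mid_hex <- function(a, b) {
  rgb_to_hex(as.integer(round((hex_to_rgb(a) + hex_to_rgb(b)) / 2)))
}
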