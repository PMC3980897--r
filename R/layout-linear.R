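#' Compute the top-down layout of a linearized path
#'
#' Stacks the path nodes top-down. Every data row has the same height; a
#' node's block grows to fit all of its mapped rows (at least
#' `min_node_height`), so a complex node with 16 mapped genes occupies
#' 16 row heights. Data columns (one per sample group, ordered by dataset
#' then group) are laid out to the right of the path axis: detailed
#' columns get a width proportional to their group size, abstract columns
#' a fixed width so abstract values line up across rows. Background shades
#' alternate per node.
#'
#' @param graph A [pathway_graph()].
#' @param spec A `linear_path_spec` from [compute_branches()].
#' @param datasets Named list of [omics_dataset()].
#' @param groupings Named list of [sample_grouping()] keyed by dataset id.
#' @param config An [enroute_config()].
#' @param styles Named character vector mapping `"<dataset>/<group>"` to
#'   `"detailed"` or `"abstract"`; unlisted groups are detailed.
#' @param alias_table Optional alias translation.
#' @return An object of class `linear_layout`.
#' @export
layout_linear <- function(graph, spec, datasets, groupings,
                          config = enroute_config(), styles = NULL,
                          alias_table = NULL) {
  rh <- config$row_height
  path_nodes <- spec$order

  # rows per node: union of resolved dataset rows, in member order
  node_rows <- lapply(path_nodes, function(nid) {
    hit <- unlist(lapply(datasets, function(ds)
      resolve_mappings(graph$nodes[[nid]], ds, alias_table, graph)))
    unique(hit)
  })
  names(node_rows) <- path_nodes

  y <- config$caption_height + 10
  blocks <- list()
  for (i in seq_along(path_nodes)) {
    n_rows <- max(1L, length(node_rows[[i]]))
    block_h <- max(config$min_node_height, n_rows * rh)
    rows_h <- n_rows * rh
    blocks[[i]] <- list(
      node_id = path_nodes[i],
      rows = node_rows[[i]],
      y_top = y, y_bottom = y + block_h,
      rows_y_top = y + (block_h - rows_h) / 2,
      shade = if (i %% 2 == 1) "light" else "dark")
    y <- y + block_h + config$node_gap
  }
  total_h <- y - config$node_gap + config$caption_height + 10

  # columns: dataset order, then the grouping's group order
  axis_x <- 10 + config$branch_slot_width
  node_w <- 80
  data_x0 <- axis_x + node_w + 40
  x <- data_x0
  cols <- list()
  for (ds_id in names(datasets)) {
    grp <- groupings[[ds_id]]
    if (is.null(grp)) next
    ds <- datasets[[ds_id]]
    for (g in names(grp$groups)) {
      key <- paste0(ds_id, "/", g)
      style <- if (!is.null(styles) && key %in% names(styles)) styles[[key]]
               else "detailed"
      n_s <- length(grp$groups[[g]])
      w <- if (style == "abstract") config$abstract_width
           else if (ds$dtype == "binary")
             max(1, ceiling(n_s / config$binary_rows)) * config$bar_width
           else n_s * config$bar_width
      cols[[length(cols) + 1L]] <- data.frame(
        dataset_id = ds_id, group = g, x_left = x, width = w,
        style = style, dtype = ds$dtype, n_samples = n_s,
        stringsAsFactors = FALSE)
      x <- x + w + config$column_gap
    }
  }
  columns <- if (length(cols)) do.call(rbind, cols) else
    data.frame(dataset_id = character(), group = character(),
               x_left = numeric(), width = numeric(), style = character(),
               dtype = character(), n_samples = integer())
  total_w <- x - config$column_gap + 14

  structure(list(spec = spec, blocks = blocks, columns = columns,
                 row_height = rh, axis_x = axis_x, node_w = node_w,
                 data_x0 = data_x0,
                 width = max(total_w, data_x0 + 40),
                 height = total_h, config = config),
            class = "linear_layout")
}

#' @export
print.linear_layout <- function(x, ...) {
  cat(sprintf("linear_layout: %d node block(s), %d column(s), %gx%g px\n",
              length(x$blocks), nrow(x$columns), x$width, x$height))
  for (b in x$blocks)
    cat(sprintf("  %s: %d row(s), y [%g, %g] (%s)\n", b$node_id,
                length(b$rows), b$y_top, b$y_bottom, b$shade))
  invisible(x)
}
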