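#' Render the linearized path view as SVG
#'
#' Draws the extracted path top-down with its data rows. Per cell (gene row
#' x sample group) the encoding depends on the dataset type and the
#' column's style:
#' \itemize{
#'   \item numerical, detailed: one vertical bar per sample from a shared
#'     zero baseline, filled with a left-to-right gradient so adjacent bars
#'     stay distinguishable;
#'   \item numerical, abstract: one horizontal mean bar with
#'     standard-deviation error whiskers;
#'   \item copy number, detailed: per-sample bars encoded redundantly by
#'     length, color and orientation (long dark red up for high gains,
#'     short light red up for low gains, nothing for normal, short light
#'     blue down for single-allele loss, long dark blue down for
#'     two-allele loss);
#'   \item copy number, abstract: a horizontal five-category histogram in
#'     the same colors;
#'   \item binary, detailed: a sample matrix (column-major fill) with
#'     mutated samples in red;
#'   \item binary, abstract: a two-bin histogram.
#' }
#' Ribbons connect each node glyph to its row block, per-node background
#' shades alternate, group captions with the dataset's color tag run along
#' the top and bottom, and samples in `highlights` are outlined wherever
#' they occur. Branch groups are drawn as countable abstract nodes beside
#' their anchor; an expanded group shows its head nodes with per-group data
#' previews while the others are grayed out.
#'
#' @param graph A [pathway_graph()].
#' @param layout A [layout_linear()] result.
#' @param datasets Named list of [omics_dataset()].
#' @param groupings Named list of [sample_grouping()].
#' @param highlights Character vector of sample ids to outline.
#' @param alias_table Optional alias translation.
#' @return SVG document as a character string.
#' @export
render_enroute <- function(graph, layout, datasets, groupings,
                           highlights = character(), alias_table = NULL) {
  cfg <- layout$config
  rh <- layout$row_height
  parts <- character()

  # shared per-dataset gradients for the detailed numerical bars
  defs <- character()
  for (ds_id in names(datasets)) {
    if (datasets[[ds_id]]$dtype != "numerical") next
    base <- datasets[[ds_id]]$color_tag
    defs <- c(defs, svg_tag("linearGradient",
      list(id = paste0("grad-", sanitize_id(ds_id)),
           x1 = 0, y1 = 0, x2 = 1, y2 = 0),
      c(svg_tag("stop", list(offset = "0", `stop-color` = darken_hex(base, 0.35))),
        svg_tag("stop", list(offset = "1", `stop-color` = base)))))
  }
  parts <- c(parts, svg_tag("defs", list(), defs))

  data_x1 <- if (nrow(layout$columns))
    max(layout$columns$x_left + layout$columns$width) else layout$data_x0

  # alternating background shades per node block
  for (b in layout$blocks) {
    shade <- if (b$shade == "light") cfg$shades[1] else cfg$shades[2]
    parts <- c(parts, svg_rect(layout$data_x0 - 6, b$y_top,
                               data_x1 - layout$data_x0 + 12,
                               b$y_bottom - b$y_top,
                               class = "row-shade", fill = shade))
  }

  # group captions (top and bottom) on the dataset's color tag
  for (ci in seq_len(nrow(layout$columns))) {
    col <- layout$columns[ci, ]
    tag <- datasets[[col$dataset_id]]$color_tag
    for (cy in c(2, layout$height - cfg$caption_height - 2)) {
      parts <- c(parts,
                 svg_rect(col$x_left, cy, col$width, cfg$caption_height,
                          class = "group-caption", fill = tag,
                          `fill-opacity` = 0.8),
                 svg_text(col$x_left + col$width / 2,
                          cy + cfg$caption_height - 4, col$group,
                          class = "caption-label", `text-anchor` = "middle",
                          `font-family` = cfg$font_family,
                          `font-size` = cfg$font_size))
    }
  }

  # path axis: node glyphs, connecting edges, ribbons
  path <- layout$spec$path
  for (i in seq_along(layout$blocks)) {
    b <- layout$blocks[[i]]
    n <- graph$nodes[[b$node_id]]
    cy <- (b$y_top + b$y_bottom) / 2
    gx <- layout$axis_x; gh <- 22
    if (i < length(layout$blocks)) {
      b2 <- layout$blocks[[i + 1]]
      forced <- is_forced(path, b$node_id, b2$node_id)
      attrs <- list(class = if (forced) "path-edge forced-edge" else "path-edge",
                    stroke = if (forced) cfg$forced_edge_color else "#333333",
                    `stroke-width` = 2)
      if (forced) attrs$`stroke-dasharray` <- "6,3"
      parts <- c(parts, do.call(svg_line,
        c(list(gx + layout$node_w / 2, cy,
               gx + layout$node_w / 2, (b2$y_top + b2$y_bottom) / 2), attrs)))
    }
    rows_h <- max(1L, length(b$rows)) * rh
    parts <- c(parts, svg_tag("polygon", list(
      points = svg_polyline_points(rbind(
        c(gx + layout$node_w, cy - gh / 2),
        c(layout$data_x0 - 6, b$rows_y_top),
        c(layout$data_x0 - 6, b$rows_y_top + rows_h),
        c(gx + layout$node_w, cy + gh / 2))),
      class = "ribbon", fill = cfg$ribbon_color,
      `fill-opacity` = cfg$ribbon_opacity)))
    parts <- c(parts,
               svg_rect(gx, cy - gh / 2, layout$node_w, gh,
                        class = paste0("path-node node-", n$kind),
                        id = paste0("pnode-", n$node_id),
                        fill = "#FFFFFF", stroke = "#000000",
                        `stroke-width` = 1.5, rx = 3),
               svg_text(gx + layout$node_w / 2, cy + cfg$font_size / 3,
                        n$label, class = "path-node-label",
                        `text-anchor` = "middle",
                        `font-family` = cfg$font_family,
                        `font-size` = cfg$font_size))
    # per-row gene labels
    for (k in seq_along(b$rows))
      parts <- c(parts, svg_text(layout$data_x0 - 10,
                                 b$rows_y_top + (k - 0.5) * rh + cfg$font_size / 3,
                                 short_gene_label(b$rows[k]),
                                 class = "row-label", `text-anchor` = "end",
                                 `font-family` = cfg$font_family,
                                 `font-size` = cfg$font_size - 2))
  }

  # branch glyphs
  parts <- c(parts, render_branches(graph, layout, datasets, groupings,
                                    alias_table))

  # data cells
  scales <- lapply(datasets, dataset_scale)
  for (ci in seq_len(nrow(layout$columns))) {
    col <- layout$columns[ci, ]
    ds <- datasets[[col$dataset_id]]
    samples <- groupings[[col$dataset_id]]$groups[[col$group]]
    for (b in layout$blocks) {
      rows <- if (length(b$rows)) b$rows else NA_character_
      for (k in seq_along(rows)) {
        y0 <- b$rows_y_top + (k - 1) * rh
        vals <- cell_values(ds, rows[k], samples)
        parts <- c(parts, render_cell(vals, ds, col, y0, rh,
                                      scales[[col$dataset_id]], highlights, cfg))
      }
    }
  }

  svg_document(layout$width, layout$height, parts)
}

cell_values <- function(ds, gene, samples) {
  v <- stats::setNames(rep(NA_real_, length(samples)), samples)
  if (!is.na(gene) && gene %in% rownames(ds$values)) {
    hit <- intersect(samples, colnames(ds$values))
    v[hit] <- ds$values[gene, hit]
  }
  v
}

# symmetric magnitude scale per dataset so bars are comparable everywhere
dataset_scale <- function(ds) {
  if (ds$dtype == "numerical") {
    m <- max(abs(ds$values), na.rm = TRUE)
    if (!is.finite(m) || m == 0) m <- 1
    m
  } else if (ds$dtype == "ordinal_cnv") 2 else 1
}

render_cell <- function(vals, ds, col, y0, rh, scale, highlights, cfg) {
  if (all(is.na(vals)))
    return(svg_rect(col$x_left, y0 + rh / 2 - 2, 4, 4,
                    class = "missing-marker", fill = cfg$missing_marker_color))
  if (col$style == "abstract") return(render_cell_abstract(vals, ds, col, y0, rh, scale, cfg))
  switch(ds$dtype,
         numerical = render_cell_bars(vals, ds, col, y0, rh, scale, highlights, cfg),
         ordinal_cnv = render_cell_cnv(vals, col, y0, rh, highlights, cfg),
         binary = render_cell_binary(vals, col, y0, rh, highlights, cfg))
}

render_cell_bars <- function(vals, ds, col, y0, rh, scale, highlights, cfg) {
  base <- y0 + rh / 2
  half <- rh / 2 - 1
  out <- character()
  for (k in seq_along(vals)) {
    v <- vals[k]
    if (is.na(v)) next
    h <- abs(v) / scale * half
    x <- col$x_left + (k - 1) * cfg$bar_width
    hl <- names(vals)[k] %in% highlights
    attrs <- list(class = if (hl) "sample-bar highlighted" else "sample-bar",
                  fill = paste0("url(#grad-", sanitize_id(ds$dataset_id), ")"))
    if (hl) { attrs$stroke <- cfg$highlight_color; attrs$`stroke-width` <- 1.5 }
    out <- c(out, do.call(svg_rect, c(
      list(x, if (v >= 0) base - h else base, max(cfg$bar_width - 1, 1), h), attrs)))
  }
  c(out, svg_line(col$x_left, base, col$x_left + col$width, base,
                  class = "cell-baseline", stroke = "#888888",
                  `stroke-width` = 0.5))
}

render_cell_cnv <- function(vals, col, y0, rh, highlights, cfg) {
  base <- y0 + rh / 2
  long <- rh / 2 - 1
  out <- character()
  for (k in seq_along(vals)) {
    v <- vals[k]
    if (is.na(v) || v == 0) next
    h <- if (abs(v) == 2) long else long / 2
    category <- cnv_code_to_category(v)
    x <- col$x_left + (k - 1) * cfg$bar_width
    hl <- names(vals)[k] %in% highlights
    attrs <- list(class = if (hl) "cnv-bar highlighted" else "cnv-bar",
                  fill = cfg$cnv_colors[[category]])
    if (hl) { attrs$stroke <- cfg$highlight_color; attrs$`stroke-width` <- 1.5 }
    out <- c(out, do.call(svg_rect, c(
      list(x, if (v > 0) base - h else base, max(cfg$bar_width - 1, 1), h), attrs)))
  }
  c(out, svg_line(col$x_left, base, col$x_left + col$width, base,
                  class = "cell-baseline", stroke = "#888888",
                  `stroke-width` = 0.5))
}

render_cell_binary <- function(vals, col, y0, rh, highlights, cfg) {
  nr <- cfg$binary_rows
  ch <- rh / nr
  cw <- cfg$bar_width
  out <- character()
  for (k in seq_along(vals)) {
    ci <- (k - 1) %/% nr
    ri <- (k - 1) %% nr
    v <- vals[k]
    fill <- if (is.na(v)) "#FFFFFF"
            else if (v == 1) cfg$mutation_color else cfg$no_mutation_color
    cls <- if (is.na(v)) "mut-cell mut-na"
           else if (v == 1) "mut-cell mut-yes" else "mut-cell mut-no"
    hl <- names(vals)[k] %in% highlights
    attrs <- list(class = if (hl) paste(cls, "highlighted") else cls,
                  fill = fill)
    if (hl) { attrs$stroke <- cfg$highlight_color; attrs$`stroke-width` <- 1.5 }
    else { attrs$stroke <- "#FFFFFF"; attrs$`stroke-width` <- 0.5 }
    out <- c(out, do.call(svg_rect, c(
      list(col$x_left + ci * cw, y0 + ri * ch, cw, ch), attrs)))
  }
  out
}

render_cell_abstract <- function(vals, ds, col, y0, rh, scale, cfg) {
  v <- vals[!is.na(vals)]
  n <- length(v)
  if (ds$dtype == "numerical") {
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    # position on [-scale, scale] across the fixed column width
    pos <- function(val) col$x_left +
      (min(max(val, -scale), scale) + scale) / (2 * scale) * col$width
    bh <- rh * 0.5
    yc <- y0 + rh / 2
    c(svg_rect(min(pos(0), pos(m)), yc - bh / 2, abs(pos(m) - pos(0)),
               bh, class = "abstract-mean-bar", fill = ds$color_tag),
      svg_line(pos(m - s), yc, pos(m + s), yc, class = "error-bar",
               stroke = "#333333", `stroke-width` = 1),
      svg_line(pos(m - s), yc - bh / 2, pos(m - s), yc + bh / 2,
               class = "error-bar", stroke = "#333333", `stroke-width` = 1),
      svg_line(pos(m + s), yc - bh / 2, pos(m + s), yc + bh / 2,
               class = "error-bar", stroke = "#333333", `stroke-width` = 1),
      svg_line(pos(0), y0 + 1, pos(0), y0 + rh - 1, class = "cell-baseline",
               stroke = "#888888", `stroke-width` = 0.5))
  } else if (ds$dtype == "ordinal_cnv") {
    counts <- vapply(-2:2, function(code) sum(v == code), integer(1))
    names(counts) <- cnv_categories
    bh <- rh / 5
    out <- character()
    for (j in seq_along(counts)) {
      if (counts[j] == 0) next
      category <- names(counts)[j]
      fill <- if (category == "normal") "#BDBDBD" else cfg$cnv_colors[[category]]
      out <- c(out, svg_rect(col$x_left, y0 + (j - 1) * bh,
                             counts[j] / n * col$width, bh,
                             class = paste0("cnv-hist-bar cnv-", category),
                             fill = fill))
    }
    out
  } else {
    mutated <- sum(v == 1)
    bh <- rh / 2
    out <- character()
    if (mutated > 0)
      out <- c(out, svg_rect(col$x_left, y0, mutated / n * col$width, bh,
                             class = "mut-hist-bar mut-hist-yes",
                             fill = cfg$mutation_color))
    if (n - mutated > 0)
      out <- c(out, svg_rect(col$x_left, y0 + bh, (n - mutated) / n * col$width,
                             bh, class = "mut-hist-bar mut-hist-no",
                             fill = cfg$no_mutation_color))
    out
  }
}

render_branches <- function(graph, layout, datasets, groupings, alias_table) {
  cfg <- layout$config
  parts <- character()
  any_expanded <- any(vapply(layout$spec$branches, `[[`, logical(1), "expanded"))
  for (br in layout$spec$branches) {
    b <- layout$blocks[[match(br$anchor, layout$spec$order)]]
    cy <- (b$y_top + b$y_bottom) / 2
    by <- if (br$direction == "joining") cy - 14 else cy + 14
    bx <- 10
    dim_others <- any_expanded && !br$expanded
    gcls <- paste0("branch-node branch-", br$direction,
                   if (br$expanded) " branch-expanded" else "",
                   if (dim_others) " branch-dimmed" else "")
    parts <- c(parts,
               svg_rect(bx, by - 9, cfg$branch_slot_width - 30, 18,
                        class = gcls,
                        fill = "#E8E8E8", stroke = "#666666",
                        `stroke-width` = 1, rx = 8,
                        `fill-opacity` = if (dim_others) 0.35 else 1),
               svg_text(bx + (cfg$branch_slot_width - 30) / 2, by + 4,
                        sprintf("%s %d",
                                if (br$direction == "joining") ">" else "<",
                                length(br$heads)),
                        class = "branch-count", `text-anchor` = "middle",
                        `font-family` = cfg$font_family,
                        `font-size` = cfg$font_size),
               svg_line(bx + cfg$branch_slot_width - 30, by,
                        layout$axis_x + layout$node_w / 2, cy,
                        class = "branch-link", stroke = "#666666",
                        `stroke-width` = 1, `stroke-dasharray` = "3,2"))
    if (br$expanded) {
      for (h in seq_along(br$heads)) {
        head_id <- br$heads[h]
        hy <- by + h * 20 * (if (br$direction == "joining") -1 else 1)
        parts <- c(parts,
                   svg_rect(bx, hy - 8, cfg$branch_slot_width - 30, 16,
                            class = "branch-head", fill = "#FFFFFF",
                            stroke = "#333333", `stroke-width` = 1, rx = 3),
                   svg_text(bx + (cfg$branch_slot_width - 30) / 2, hy + 3,
                            graph$nodes[[head_id]]$label,
                            class = "branch-head-label",
                            `text-anchor` = "middle",
                            `font-family` = cfg$font_family,
                            `font-size` = cfg$font_size - 2))
        pv <- branch_preview(graph$nodes[[head_id]], datasets, groupings,
                             alias_table, graph)
        px <- bx + cfg$branch_slot_width - 26
        for (ds_id in names(pv)) {
          if (pv[[ds_id]]$no_data) next
          for (g in names(pv[[ds_id]]$groups)) {
            p <- pv[[ds_id]]$groups[[g]]
            if (isTRUE(p$no_data)) next
            w <- if (p$kind == "mean_bar") max(abs(p$mean), 0.05) * 4 else 8
            parts <- c(parts, svg_rect(px, hy - 5, min(w, 16), 10,
                                       class = paste0("branch-preview preview-", p$kind),
                                       fill = datasets[[ds_id]]$color_tag))
            px <- px + 6
          }
        }
      }
    }
  }
  parts
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9_-]", "_", x)

short_gene_label <- function(id) sub("^[a-z0-9_]+:", "", id)

darken_hex <- function(hex, f) {
  rgb_to_hex(as.integer(round(hex_to_rgb(hex) * (1 - f))))
}
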