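read_svg <- function(svg) {
  doc <- xml2::read_xml(svg)
  xml2::xml_ns_strip(doc)
  doc
}

svg_count <- function(doc, class) {
  length(xml2::xml_find_all(doc, sprintf("//*[contains(@class,'%s')]", class)))
}

test_that("the diverging map hits its anchors exactly and is linear between", {
  spec <- diverging_spec("#2166AC", "#FFFFFF", "#B2182B", -2, 0, 2)
  expect_equal(diverging_color(0, spec), "#FFFFFF")
  expect_equal(diverging_color(2, spec), "#B2182B")
  expect_equal(diverging_color(-2, spec), "#2166AC")
  # clamping
  expect_equal(diverging_color(99, spec), "#B2182B")
  # halfway to the maximum: channel-wise midpoint of mid and high
  mid_expect <- sprintf("#%02X%02X%02X",
                        round((255 + 0xB2) / 2), round((255 + 0x18) / 2),
                        round((255 + 0x2B) / 2))
  expect_equal(diverging_color(1, spec), mid_expect)
  expect_error(diverging_spec(vmin = 1, vmid = 0, vmax = 2), "vmin < vmid")
})

test_that("overview node fills equal an independent color recomputation", {
  g <- mk_graph(c("A", "B", "C"), c("A>B", "B>C"),
                members = list("g1", "g2", "g3"))
  m <- mk_matrix(c("g1", "g2"), c("s1", "s2"), c(1, 1, -2, 0))
  ds <- mk_dataset(m, id = "expr")
  svg <- render_overview(g, ds)
  doc <- read_svg(svg)
  rects <- xml2::xml_find_all(doc, "//rect[contains(@class,'node-rect')]")
  fills <- stats::setNames(xml2::xml_attr(rects, "fill"),
                           sub("^node-", "", xml2::xml_attr(rects, "id")))
  means <- c(A = 1, B = -1)
  cfg <- enroute_config()
  spec <- diverging_spec(cfg$diverging$low, cfg$diverging$mid,
                         cfg$diverging$high, -max(abs(means)), 0,
                         max(abs(means)))
  expect_identical(fills[["A"]], diverging_color(1, spec))
  expect_identical(fills[["B"]], diverging_color(-1, spec))
  # unmapped node: white with a missing marker
  expect_identical(fills[["C"]], "#FFFFFF")
  expect_gte(svg_count(doc, "missing-marker"), 1)
})

test_that("variance bars scale against the pathway maximum", {
  g <- mk_graph(c("A", "B"), members = list("g1", "g2"))
  m <- mk_matrix(c("g1", "g2"), paste0("s", 1:4),
                 c(0, 0, 2, 2,   1, 1, 1, 1))  # std 1 vs std 0
  svg <- render_overview(g, mk_dataset(m))
  doc <- read_svg(svg)
  bars <- xml2::xml_find_all(doc, "//rect[contains(@class,'variance-bar')]")
  expect_length(bars, 1)  # zero-variance node draws no bar
  expect_equal(as.numeric(xml2::xml_attr(bars, "width")),
               unname(g$nodes[["A"]]$bbox[3]))  # full width for the maximum
})

test_that("rendering is byte-deterministic for identical inputs", {
  cfg <- fixture_config(seed = 9)
  g <- make_pathway(cfg)
  om <- make_omics(g, cfg)
  alts <- find_alternatives(g, "n01", "n04")
  p <- current_path(alts)
  spec <- compute_branches(g, p)
  lay <- layout_linear(g, spec, om$datasets, om$groupings)
  a <- render_enroute(g, lay, om$datasets, om$groupings)
  b <- render_enroute(g, lay, om$datasets, om$groupings)
  expect_identical(a, b)
  oa <- render_overview(g, om$datasets$mrna, om$groupings$mrna, selection = alts)
  ob <- render_overview(g, om$datasets$mrna, om$groupings$mrna, selection = alts)
  expect_identical(oa, ob)
})

test_that("detailed cells account for every sample", {
  cfg <- fixture_config(seed = 21, missing_rate = 0.1)
  g <- make_pathway(cfg)
  om <- make_omics(g, cfg)
  p <- current_path(find_alternatives(g, "n01", "n04"))
  spec <- compute_branches(g, p)
  lay <- layout_linear(g, spec, om$datasets, om$groupings)
  doc <- read_svg(render_enroute(g, lay, om$datasets, om$groupings))

  rows <- unlist(lapply(lay$blocks, `[[`, "rows"))
  samples <- colnames(om$datasets$mrna$values)
  # numerical bars = non-missing cells over mapped rows
  expected_bars <- sum(!is.na(om$datasets$mrna$values[rows, samples]))
  expect_equal(svg_count(doc, "sample-bar"), expected_bars)
  # mutation matrix draws one cell per sample, missing included
  n_cells <- svg_count(doc, "mut-cell")
  expect_equal(n_cells, length(rows) * length(samples))
  # mutated cell count equals the data
  expect_equal(svg_count(doc, "mut-yes"),
               sum(om$datasets$mutation$values[rows, samples] == 1,
                   na.rm = TRUE))
})

test_that("copy-number bars follow the redundant length/color/orientation code", {
  g <- mk_graph("A", members = list("g1"))
  m <- mk_matrix("g1", paste0("s", 1:3), c(2, 0, -2))
  ds <- omics_dataset("cnv", "ordinal_cnv", m)
  grp <- list(cnv = sample_grouping("cnv", list(all = paste0("s", 1:3)), ds))
  spec <- compute_branches(g, selected_path(g, "A"))
  lay <- layout_linear(g, spec, list(cnv = ds), grp)
  doc <- read_svg(render_enroute(g, lay, list(cnv = ds), grp))
  bars <- xml2::xml_find_all(doc, "//rect[contains(@class,'cnv-bar')]")
  expect_length(bars, 2)  # the normal sample draws nothing
  fills <- xml2::xml_attr(bars, "fill")
  cfg <- enroute_config()
  expect_setequal(fills, c(cfg$cnv_colors[["high_gain"]],
                           cfg$cnv_colors[["hom_del"]]))
  ys <- as.numeric(xml2::xml_attr(bars, "y"))
  hs <- as.numeric(xml2::xml_attr(bars, "height"))
  base <- lay$blocks[[1]]$rows_y_top + lay$row_height / 2
  up <- which(fills == cfg$cnv_colors[["high_gain"]])
  down <- which(fills == cfg$cnv_colors[["hom_del"]])
  expect_equal(ys[up] + hs[up], base)  # gain points up from the baseline
  expect_equal(ys[down], base)         # deletion points down
  expect_equal(hs[up], hs[down])       # both are the long form
})

test_that("abstract columns share a fixed width and baseline", {
  cfg <- fixture_config(seed = 22)
  g <- make_pathway(cfg)
  om <- make_omics(g, cfg)
  p <- current_path(find_alternatives(g, "n01", "n04"))
  spec <- compute_branches(g, p)
  styles <- c("mrna/tumor" = "abstract", "mrna/normal" = "abstract",
              "cnv/tumor" = "abstract")
  lay <- layout_linear(g, spec, om$datasets, om$groupings, styles = styles)
  ab <- lay$columns[lay$columns$style == "abstract", ]
  expect_equal(nrow(ab), 3)
  expect_true(all(ab$width == enroute_config()$abstract_width))
  # detailed width stays proportional to group size (equal groups here)
  det <- lay$columns[lay$columns$style == "detailed" &
                       lay$columns$dtype == "ordinal_cnv", ]
  expect_equal(det$width, det$n_samples * enroute_config()$bar_width)
})

test_that("detailed column widths scale with group size", {
  m <- mk_matrix("g1", paste0("s", 1:40), stats::rnorm(40))
  ds <- mk_dataset(m, id = "expr")
  grp <- list(expr = sample_grouping("expr", list(small = paste0("s", 1:10),
                                                  large = paste0("s", 11:40)), ds))
  g <- mk_graph("A", members = list("g1"))
  lay <- layout_linear(g, compute_branches(g, selected_path(g, "A")),
                       list(expr = ds), grp)
  w <- lay$columns$width
  expect_equal(w[2] / w[1], 3)
})

test_that("node blocks alternate shades and grow with their rows", {
  cfg <- fixture_config(seed = 23)
  g <- make_pathway(cfg)
  om <- make_omics(g, cfg)
  alts <- find_alternatives(g, "n01", "n04", max_len = 8)
  p <- current_path(alts)
  spec <- compute_branches(g, p)
  lay <- layout_linear(g, spec, om$datasets, om$groupings)
  shades <- vapply(lay$blocks, `[[`, character(1), "shade")
  expect_equal(shades, rep(c("light", "dark"), length.out = length(shades)))
  rh <- lay$row_height
  for (b in lay$blocks) {
    expect_gte(b$y_bottom - b$y_top,
               max(enroute_config()$min_node_height, length(b$rows) * rh))
  }
  # vertical intervals disjoint and ordered
  tops <- vapply(lay$blocks, `[[`, numeric(1), "y_top")
  bottoms <- vapply(lay$blocks, `[[`, numeric(1), "y_bottom")
  expect_true(all(tops[-1] > bottoms[-length(bottoms)]))
})

test_that("a 16-gene complex node yields 16 uniform rows", {
  cfg <- fixture_config(seed = 24, complex_members = 16)
  g <- make_pathway(cfg)
  om <- make_omics(g, cfg)
  # route the path through the complex node n05
  p <- selected_path(g, "n05")
  spec <- compute_branches(g, p)
  lay <- layout_linear(g, spec, om$datasets, om$groupings)
  b <- lay$blocks[[1]]
  expect_length(b$rows, 16)
  expect_equal(b$y_bottom - b$y_top, 16 * lay$row_height)
})

test_that("expanded branches draw their heads; others are grayed out", {
  g <- mk_graph(c("P", "i1", "i2", "o1", "o2", "N"),
                c("i1>P", "i2>P", "P>o1", "P>o2", "P>N"))
  ds <- mk_dataset(mk_matrix("g1", c("s1", "s2"), c(1, 2)), id = "expr")
  grp <- list(expr = sample_grouping("expr", list(all = c("s1", "s2")), ds))
  spec <- compute_branches(g, selected_path(g, c("P", "N")))
  spec <- expand_branch(spec, "P", "leaving")
  lay <- layout_linear(g, spec, list(expr = ds), grp)
  doc <- read_svg(render_enroute(g, lay, list(expr = ds), grp))
  heads <- xml2::xml_find_all(doc, "//rect[contains(@class,'branch-head')]")
  expect_length(heads, 2)                            # o1, o2 revealed
  expect_gte(svg_count(doc, "branch-dimmed"), 1)     # joining group grayed
  counts <- xml2::xml_text(xml2::xml_find_all(
    doc, "//text[contains(@class,'branch-count')]"))
  expect_true(any(grepl("2", counts)))               # group reports |heads|
})

test_that("highlighted samples are outlined wherever they occur", {
  cfg <- fixture_config(seed = 25, missing_rate = 0)
  g <- make_pathway(cfg)
  om <- make_omics(g, cfg)
  p <- current_path(find_alternatives(g, "n01", "n04"))
  lay <- layout_linear(g, compute_branches(g, p), om$datasets, om$groupings)
  doc <- read_svg(render_enroute(g, lay, om$datasets, om$groupings,
                                 highlights = "s001"))
  n_rows <- length(unlist(lapply(lay$blocks, `[[`, "rows")))
  # one outline per dataset per row (mrna bar, cnv slot when drawn, mutation cell)
  expect_gte(svg_count(doc, "highlighted"), 2 * n_rows)
})
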