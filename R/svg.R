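# Minimal deterministic SVG serializer. Attributes are emitted in the
# order given; all numbers go through svg_num() so identical inputs yield
# byte-identical documents.

svg_num <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("\\.?0+$", "", s)
  ifelse(s == "-0", "0", s)
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_attrs <- function(attrs) {
  if (!length(attrs)) return("")
  vals <- vapply(attrs, function(v)
    if (is.numeric(v)) svg_num(v) else as.character(v), character(1))
  paste0(" ", paste0(names(attrs), '="', vals, '"', collapse = " "))
}

svg_tag <- function(name, attrs = list(), children = character()) {
  if (!length(children))
    paste0("<", name, svg_attrs(attrs), "/>")
  else
    paste0("<", name, svg_attrs(attrs), ">",
           paste(children, collapse = ""), "</", name, ">")
}

svg_rect <- function(x, y, w, h, ...) {
  svg_tag("rect", c(list(x = x, y = y, width = w, height = h), list(...)))
}

svg_line <- function(x1, y1, x2, y2, ...) {
  svg_tag("line", c(list(x1 = x1, y1 = y1, x2 = x2, y2 = y2), list(...)))
}

svg_text <- function(x, y, label, ...) {
  svg_tag("text", c(list(x = x, y = y), list(...)), svg_escape(label))
}

svg_polyline_points <- function(pts) {
  paste(apply(pts, 1, function(p) paste0(svg_num(p[1]), ",", svg_num(p[2]))),
        collapse = " ")
}

svg_path_from_rings <- function(rings) {
  paste(vapply(rings, function(ring) {
    coords <- apply(ring, 1, function(p) paste0(svg_num(p[1]), " ", svg_num(p[2])))
    paste0("M ", paste(coords, collapse = " L "), " Z")
  }, character(1)), collapse = " ")
}

svg_document <- function(width, height, children) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<svg xmlns="http://www.w3.org/2000/svg" width="', svg_num(width),
         '" height="', svg_num(height), '" viewBox="0 0 ', svg_num(width),
         " ", svg_num(height), '">\n',
         paste(children, collapse = "\n"), "\n</svg>\n")
}
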