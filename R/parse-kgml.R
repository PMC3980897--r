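#' Parse a KGML pathway description
#'
#' Reads a KEGG Markup Language document into a [pathway_graph()]. Entries of
#' type `gene` (and `ortholog`/`enzyme`), `compound`, `map` and `group`
#' become nodes; `relation` elements and `reaction` substrate/product pairs
#' become edges. Graphics coordinates are copied verbatim (center-based
#' image pixels). Space-separated identifiers in an entry `name` become the
#' node's member list; the KEGG `hsa:` prefix is normalized to `entrez:`,
#' tokens without a namespace become `symbol:<token>`.
#'
#' @param x File path, XML string or `xml2::xml_document`.
#' @return A [pathway_graph()] with `source_format = "kgml"`.
#' @export
parse_kgml <- function(x) {
  doc <- read_pathway_xml(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway")
    stop("not a KGML document: root element is <", xml2::xml_name(root), ">")

  kind_map <- c(gene = "gene", ortholog = "gene", enzyme = "gene",
                compound = "compound", map = "map_link", group = "group")
  nodes <- list()
  id_index <- character()  # KGML entry id -> node_id

  for (entry in xml2::xml_find_all(root, "./entry")) {
    type <- xml2::xml_attr(entry, "type")
    if (!type %in% names(kind_map)) next
    kind <- kind_map[[type]]
    eid <- xml2::xml_attr(entry, "id")
    g <- xml2::xml_find_first(entry, "./graphics")
    if (inherits(g, "xml_missing") || is.na(xml2::xml_attr(g, "x"))) {
      warning("KGML entry ", eid, " has no graphics coordinates; skipped")
      next
    }
    bbox <- as.numeric(c(xml2::xml_attr(g, "x"), xml2::xml_attr(g, "y"),
                         xml2::xml_attr(g, "width"), xml2::xml_attr(g, "height")))
    glabel <- xml2::xml_attr(g, "name")
    label <- if (is.na(glabel) || !nzchar(glabel)) eid else
      sub("\\.\\.\\.$", "", strsplit(glabel, ",")[[1]][1])
    members <- character()
    if (kind == "gene") {
      nm <- xml2::xml_attr(entry, "name")
      toks <- if (is.na(nm)) character() else
        strsplit(trimws(nm), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks) & toks != "undefined"]
      members <- vapply(toks, normalize_kegg_id, character(1), USE.NAMES = FALSE)
      if (!length(members)) members <- paste0("symbol:", label)
    }
    children <- xml2::xml_attr(xml2::xml_find_all(entry, "./component"), "id")
    nodes[[length(nodes) + 1L]] <-
      pathway_node(eid, kind, label, bbox, members, children)
    id_index[eid] <- eid
  }

  # group children reference entry ids; drop ones whose entry was skipped
  nodes <- lapply(nodes, function(n) {
    if (n$kind == "group") n$children <- n$children[n$children %in% names(id_index)]
    n
  })

  edges <- list()
  for (rel in xml2::xml_find_all(root, "./relation")) {
    a <- xml2::xml_attr(rel, "entry1"); b <- xml2::xml_attr(rel, "entry2")
    if (!a %in% names(id_index) || !b %in% names(id_index)) {
      warning("relation ", a, " -> ", b, " references a missing entry; dropped")
      next
    }
    sub_names <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    directed_attr <- xml2::xml_attr(rel, "directed")
    edges[[length(edges) + 1L]] <- data.frame(
      source = a, target = b,
      relation = kgml_relation(sub_names),
      directed = is.na(directed_attr) || !identical(directed_attr, "false"),
      stringsAsFactors = FALSE)
  }
  for (rxn in xml2::xml_find_all(root, "./reaction")) {
    gene_id <- xml2::xml_attr(rxn, "id")
    rev <- identical(xml2::xml_attr(rxn, "type"), "reversible")
    if (!gene_id %in% names(id_index)) next
    for (s in xml2::xml_attr(xml2::xml_find_all(rxn, "./substrate"), "id"))
      if (s %in% names(id_index))
        edges[[length(edges) + 1L]] <- data.frame(
          source = s, target = gene_id, relation = "conversion",
          directed = !rev, stringsAsFactors = FALSE)
    for (p in xml2::xml_attr(xml2::xml_find_all(rxn, "./product"), "id"))
      if (p %in% names(id_index))
        edges[[length(edges) + 1L]] <- data.frame(
          source = gene_id, target = p, relation = "conversion",
          directed = !rev, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges()

  w <- as.numeric(xml2::xml_attr(root, "width"))
  h <- as.numeric(xml2::xml_attr(root, "height"))
  image_size <- if (!is.na(w) && !is.na(h)) c(w, h) else NULL
  title <- xml2::xml_attr(root, "title")
  pid <- xml2::xml_attr(root, "name")
  pathway_graph(if (is.na(pid)) "pathway" else pid,
                if (is.na(title)) "" else title,
                nodes, edges, image_size, "kgml")
}

normalize_kegg_id <- function(tok) {
  if (grepl("^hsa:", tok)) sub("^hsa:", "entrez:", tok)
  else if (grepl(":", tok, fixed = TRUE)) tok
  else paste0("symbol:", tok)
}

kgml_relation <- function(sub_names) {
  sub_names <- sub_names[!is.na(sub_names)]
  if (any(sub_names %in% c("activation", "expression")))       "activation"
  else if (any(sub_names %in% c("inhibition", "repression")))  "inhibition"
  else if (any(sub_names %in% c("binding/association", "binding"))) "binding"
  else if (any(sub_names %in% c("compound", "conversion")))    "conversion"
  else "other"
}

read_pathway_xml <- function(x) {
  if (inherits(x, "xml_document")) return(x)
  tryCatch(xml2::read_xml(x),
           error = function(e) stop("XML parse error: ", conditionMessage(e),
                                    call. = FALSE))
}

#' Serialize a pathway graph as KGML
#'
#' Writes the package's KGML dialect, chosen so that
#' `parse_kgml(write_kgml(g))` reproduces `g` (node ids, members, bounding
#' boxes, edges). Members are written verbatim into the entry `name`
#' attribute; undirected edges carry `directed="false"`; the edge relation
#' is stored as a `subtype` element.
#'
#' @param graph A [pathway_graph()].
#' @param file Optional path; if given the document is written there.
#' @return The XML document as a character string (invisibly when `file`
#'   is given).
#' @export
write_kgml <- function(graph, file = NULL) {
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  kind_out <- c(gene = "gene", compound = "compound",
                map_link = "map", group = "group")
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<pathway name="%s" title="%s" width="%s" height="%s">',
                     esc(graph$pathway_id), esc(graph$title),
                     num(graph$image_size[1]), num(graph$image_size[2])))
  for (n in graph$nodes) {
    nm <- if (n$kind == "gene") paste(n$members, collapse = " ") else "undefined"
    open <- sprintf('  <entry id="%s" name="%s" type="%s">',
                    esc(n$node_id), esc(nm), kind_out[[n$kind]])
    gfx <- sprintf('    <graphics name="%s" type="rectangle" x="%s" y="%s" width="%s" height="%s"/>',
                   esc(n$label), num(n$bbox[1]), num(n$bbox[2]),
                   num(n$bbox[3]), num(n$bbox[4]))
    comps <- if (length(n$children))
      sprintf('    <component id="%s"/>', esc(n$children)) else character()
    lines <- c(lines, open, gfx, comps, "  </entry>")
  }
  e <- graph$edges
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    dir_attr <- if (e$directed[i]) "" else ' directed="false"'
    lines <- c(lines,
               sprintf('  <relation entry1="%s" entry2="%s" type="PPrel"%s>',
                       esc(e$source[i]), esc(e$target[i]), dir_attr),
               sprintf('    <subtype name="%s" value="--&gt;"/>', e$relation[i]),
               "  </relation>")
  }
  lines <- c(lines, "</pathway>")
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}
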