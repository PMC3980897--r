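#' Parse a GPML (WikiPathways) pathway description
#'
#' Reads a GPML document into a [pathway_graph()]. `DataNode` elements of
#' type `GeneProduct`, `Protein` or `Rna` become gene nodes, `Metabolite`
#' becomes a compound, `Pathway` a map link. `Group` elements become group
#' nodes whose children are the DataNodes carrying the matching `GroupRef`.
#' Interaction endpoints are taken from the first and last `Point`; a
#' `GraphRef` to an `Anchor` is resolved to the target node of the anchor's
#' host interaction. An interaction whose endpoints cannot be resolved is
#' dropped with a warning. Coordinates (`CenterX`/`CenterY`/`Width`/`Height`)
#' are adopted unchanged.
#'
#' Members come from the `Xref` element (`Entrez Gene` maps to the `entrez:`
#' namespace, other databases to a lower-cased namespace tag); a node
#' without a usable Xref falls back to `symbol:<TextLabel>`.
#'
#' @param x File path, XML string or `xml2::xml_document`.
#' @return A [pathway_graph()] with `source_format = "gpml"`.
#' @export
parse_gpml <- function(x) {
  doc <- read_pathway_xml(x)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Pathway")
    stop("not a GPML document: root element is <", xml2::xml_name(root), ">")

  type_map <- c(GeneProduct = "gene", Protein = "gene", Rna = "gene",
                Metabolite = "compound", Pathway = "map_link")
  nodes <- list()
  group_children <- list()  # GroupRef -> node ids
  auto <- 0L

  for (dn in xml2::xml_find_all(root, "./DataNode")) {
    type <- xml2::xml_attr(dn, "Type")
    kind <- if (is.na(type) || !type %in% names(type_map)) "gene" else type_map[[type]]
    label <- xml2::xml_attr(dn, "TextLabel")
    if (is.na(label)) label <- ""
    gid <- xml2::xml_attr(dn, "GraphId")
    if (is.na(gid)) { auto <- auto + 1L; gid <- sprintf("dn%04d", auto) }
    g <- xml2::xml_find_first(dn, "./Graphics")
    if (inherits(g, "xml_missing") || is.na(xml2::xml_attr(g, "CenterX"))) {
      warning("GPML DataNode ", gid, " has no coordinates; skipped")
      next
    }
    bbox <- as.numeric(c(xml2::xml_attr(g, "CenterX"), xml2::xml_attr(g, "CenterY"),
                         xml2::xml_attr(g, "Width"), xml2::xml_attr(g, "Height")))
    members <- character()
    if (kind == "gene") {
      xr <- xml2::xml_find_first(dn, "./Xref")
      db <- if (inherits(xr, "xml_missing")) NA else xml2::xml_attr(xr, "Database")
      id <- if (inherits(xr, "xml_missing")) NA else xml2::xml_attr(xr, "ID")
      members <- if (!is.na(db) && !is.na(id) && nzchar(db) && nzchar(id))
        paste0(gpml_namespace(db), ":", id) else paste0("symbol:", label)
    }
    nodes[[length(nodes) + 1L]] <- pathway_node(gid, kind, label, bbox, members)
    gref <- xml2::xml_attr(dn, "GroupRef")
    if (!is.na(gref)) group_children[[gref]] <- c(group_children[[gref]], gid)
  }
  node_ids <- vapply(nodes, function(n) n$node_id, character(1))

  group_lookup <- character()  # GroupId/GraphId -> group node id
  for (grp in xml2::xml_find_all(root, "./Group")) {
    group_id <- xml2::xml_attr(grp, "GroupId")
    graph_id <- xml2::xml_attr(grp, "GraphId")
    gid <- if (!is.na(graph_id)) graph_id else group_id
    kids <- group_children[[group_id]]
    kids <- kids[kids %in% node_ids]
    if (!length(kids)) next
    bb <- vapply(nodes[match(kids, node_ids)], function(n) n$bbox, numeric(4))
    x0 <- min(bb[1, ] - bb[3, ] / 2); x1 <- max(bb[1, ] + bb[3, ] / 2)
    y0 <- min(bb[2, ] - bb[4, ] / 2); y1 <- max(bb[2, ] + bb[4, ] / 2)
    pad <- 8
    nodes[[length(nodes) + 1L]] <- pathway_node(
      gid, "group", if (is.na(group_id)) gid else group_id,
      c((x0 + x1) / 2, (y0 + y1) / 2, x1 - x0 + pad, y1 - y0 + pad),
      children = kids)
    node_ids <- c(node_ids, gid)
    group_lookup[group_id] <- gid
    if (!is.na(graph_id)) group_lookup[graph_id] <- gid
  }

  resolve_ref <- function(ref) {
    if (is.na(ref)) return(NA_character_)
    if (ref %in% node_ids) return(ref)
    if (ref %in% names(group_lookup)) return(group_lookup[[ref]])
    NA_character_
  }

  inters <- xml2::xml_find_all(root, "./Interaction")
  ends <- lapply(inters, function(it) {
    pts <- xml2::xml_find_all(it, "./Graphics/Point")
    if (length(pts) < 2) return(NULL)
    list(src = xml2::xml_attr(pts[[1]], "GraphRef"),
         dst = xml2::xml_attr(pts[[length(pts)]], "GraphRef"),
         head = xml2::xml_attr(pts[[length(pts)]], "ArrowHead"),
         anchors = xml2::xml_attr(xml2::xml_find_all(it, "./Graphics/Anchor"),
                                  "GraphId"))
  })
  # anchor id -> (resolved endpoints of its host interaction)
  anchor_host <- list()
  for (e in ends) if (!is.null(e))
    for (a in e$anchors) if (!is.na(a))
      anchor_host[[a]] <- c(resolve_ref(e$src), resolve_ref(e$dst))

  edges <- list()
  for (e in ends) {
    if (is.null(e)) next
    src <- resolve_ref(e$src); dst <- resolve_ref(e$dst)
    if (is.na(src) && !is.na(e$src) && e$src %in% names(anchor_host)) {
      h <- anchor_host[[e$src]]; src <- if (!is.na(h[2])) h[2] else h[1]
    }
    if (is.na(dst) && !is.na(e$dst) && e$dst %in% names(anchor_host)) {
      h <- anchor_host[[e$dst]]; dst <- if (!is.na(h[2])) h[2] else h[1]
    }
    if (is.na(src) || is.na(dst) || src == dst) {
      warning("GPML interaction with unresolvable endpoint (",
              e$src, " -> ", e$dst, "); dropped")
      next
    }
    rel_dir <- gpml_arrowhead(e$head)
    edges[[length(edges) + 1L]] <- data.frame(
      source = src, target = dst, relation = rel_dir$relation,
      directed = rel_dir$directed, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges()

  g <- xml2::xml_find_first(root, "./Graphics")
  image_size <- if (!inherits(g, "xml_missing")) {
    bw <- as.numeric(xml2::xml_attr(g, "BoardWidth"))
    bh <- as.numeric(xml2::xml_attr(g, "BoardHeight"))
    if (!is.na(bw) && !is.na(bh)) c(bw, bh) else NULL
  } else NULL
  title <- xml2::xml_attr(root, "Name")
  pathway_graph(if (is.na(title)) "pathway" else title,
                if (is.na(title)) "" else title,
                nodes, edges, image_size, "gpml")
}

gpml_namespace <- function(db) {
  key <- tolower(trimws(db))
  switch(key,
         "entrez gene" = "entrez",
         "ensembl" = "ensembl",
         "uniprot" = "uniprot",
         "hgnc" = "symbol",
         gsub("[^a-z0-9]+", "_", key))
}

gpml_arrowhead <- function(head) {
  if (is.na(head) || head %in% c("", "Line"))
    return(list(relation = "other", directed = FALSE))
  if (head %in% c("Arrow", "mim-stimulation", "mim-activation", "mim-conversion"))
    list(relation = if (head == "mim-conversion") "conversion" else "activation",
         directed = TRUE)
  else if (head %in% c("TBar", "mim-inhibition"))
    list(relation = "inhibition", directed = TRUE)
  else if (head %in% c("mim-binding"))
    list(relation = "binding", directed = TRUE)
  else list(relation = "other", directed = TRUE)
}
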