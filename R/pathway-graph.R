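#' Construct a pathway node
#'
#' A node of a pathway map, carrying its bounding box in the original image
#' coordinate system (origin top-left, y increasing downward, anchor at the
#' box center, as in KGML graphics elements).
#'
#' @param node_id Unique id within the pathway (character scalar).
#' @param kind One of `"gene"`, `"compound"`, `"map_link"`, `"group"`.
#' @param label Display label.
#' @param bbox Numeric vector `c(x, y, width, height)`; `x`/`y` are the box
#'   center in image pixels.
#' @param members Character vector of namespace-qualified gene identifiers
#'   (e.g. `"entrez:1956"`). A gene node may carry several members
#'   (multi-mapping). Must be empty for compounds and map links.
#' @param children Character vector of child node ids; non-empty only for
#'   `kind = "group"` (complex nodes).
#' @return An object of class `pathway_node`.
#' @export
pathway_node <- function(node_id, kind, label = node_id,
                         bbox = c(0, 0, 46, 17),
                         members = character(), children = character()) {
  kind <- match.arg(kind, c("gene", "compound", "map_link", "group"))
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || any(!is.finite(bbox)) || bbox[3] <= 0 || bbox[4] <= 0)
    stop("bbox must be c(x, y, width, height) with positive width and height")
  if (kind %in% c("compound", "map_link") && length(members) > 0)
    stop("members must be empty for kind=", kind)
  if (kind == "gene" && length(members) < 1)
    stop("gene node '", node_id, "' needs at least one member identifier")
  names(bbox) <- c("x", "y", "width", "height")
  structure(list(node_id = as.character(node_id), kind = kind,
                 label = as.character(label), bbox = bbox,
                 members = as.character(members),
                 children = as.character(children)),
            class = "pathway_node")
}

#' Construct a pathway graph
#'
#' @param pathway_id Pathway identifier.
#' @param title Pathway title.
#' @param nodes List of [pathway_node()] objects.
#' @param edges `data.frame` with columns `source`, `target`, `relation`
#'   (`activation`, `inhibition`, `binding`, `conversion`, `other`) and
#'   `directed` (logical). Undirected edges are stored once and traversable
#'   both ways.
#' @param image_size `c(width, height)` of the original map image in pixels;
#'   if `NULL`, taken as the extent of the node boxes.
#' @param source_format `"kgml"` or `"gpml"`.
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, title = pathway_id, nodes = list(),
                          edges = empty_edges(), image_size = NULL,
                          source_format = c("kgml", "gpml")) {
  source_format <- match.arg(source_format)
  ids <- vapply(nodes, function(n) n$node_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate node ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(nodes) <- ids
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    bad <- !(edges$source %in% ids) | !(edges$target %in% ids)
    if (any(bad)) stop("edge endpoints not in node set: ",
                       paste(unique(c(edges$source[bad], edges$target[bad])), collapse = ", "))
  }
  for (n in nodes) {
    if (n$kind == "group" && !all(n$children %in% ids))
      stop("group '", n$node_id, "' references missing children")
  }
  child_of <- unlist(lapply(nodes, function(n) if (n$kind == "group") n$children))
  if (anyDuplicated(child_of))
    stop("a node may not be a child of two groups")
  if (is.null(image_size)) {
    if (length(nodes)) {
      bb <- vapply(nodes, function(n) n$bbox, numeric(4))
      image_size <- c(max(bb[1, ] + bb[3, ] / 2), max(bb[2, ] + bb[4, ] / 2))
    } else image_size <- c(1, 1)
  }
  structure(list(pathway_id = as.character(pathway_id),
                 title = as.character(title),
                 image_size = as.numeric(image_size),
                 nodes = nodes, edges = edges,
                 source_format = source_format),
            class = "pathway_graph")
}

empty_edges <- function() {
  data.frame(source = character(), target = character(),
             relation = character(), directed = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.pathway_graph <- function(x, ...) {
  kinds <- table(vapply(x$nodes, function(n) n$kind, character(1)))
  cat(sprintf("pathway_graph '%s' (%s): %d nodes, %d edges, image %gx%g px\n",
              x$pathway_id, x$source_format, length(x$nodes), nrow(x$edges),
              x$image_size[1], x$image_size[2]))
  if (length(kinds)) cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pathway_node <- function(x, ...) {
  cat(sprintf("pathway_node '%s' [%s] '%s' @(%g,%g) %gx%g",
              x$node_id, x$kind, x$label, x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  if (length(x$members)) cat(" members:", paste(x$members, collapse = ","))
  if (length(x$children)) cat(" children:", paste(x$children, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Adjacent nodes of a pathway node
#'
#' Directed edges are followed from source to target; undirected edges are
#' traversable both ways. The result is sorted by neighbor node id so the
#' ordering is independent of edge insertion order.
#'
#' @param graph A [pathway_graph()].
#' @param node_id Node whose neighborhood to list.
#' @param direction `"out"` (successors), `"in"` (predecessors) or `"both"`.
#' @return `data.frame` with columns `node` (neighbor id), `relation`,
#'   `directed` and `edge` (row index into `graph$edges`).
#' @export
neighbors <- function(graph, node_id, direction = c("out", "in", "both")) {
  direction <- match.arg(direction)
  if (!node_id %in% names(graph$nodes)) stop("unknown node: ", node_id)
  e <- graph$edges
  res <- data.frame(node = character(), relation = character(),
                    directed = logical(), edge = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(e)) {
    pick <- function(idx, nb) {
      if (!length(idx)) return(NULL)
      data.frame(node = nb, relation = e$relation[idx],
                 directed = e$directed[idx], edge = idx,
                 stringsAsFactors = FALSE)
    }
    out_d <- which(e$source == node_id & e$directed)
    in_d  <- which(e$target == node_id & e$directed)
    un_s  <- which(e$source == node_id & !e$directed)
    un_t  <- which(e$target == node_id & !e$directed)
    parts <- list()
    if (direction %in% c("out", "both"))
      parts <- c(parts, list(pick(out_d, e$target[out_d]),
                             pick(un_s, e$target[un_s]), pick(un_t, e$source[un_t])))
    if (direction %in% c("in", "both"))
      parts <- c(parts, list(pick(in_d, e$source[in_d]),
                             pick(un_s, e$target[un_s]), pick(un_t, e$source[un_t])))
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) {
      res <- do.call(rbind, parts)
      res <- res[!duplicated(res[c("node", "edge")]), , drop = FALSE]
      res <- res[order(res$node, res$edge), , drop = FALSE]
      rownames(res) <- NULL
    }
  }
  res
}

#' Edge lookup helper: is (a, b) traversable a -> b?
#' @noRd
has_edge <- function(graph, a, b) {
  e <- graph$edges
  any((e$source == a & e$target == b & e$directed) |
      (!e$directed & ((e$source == a & e$target == b) |
                      (e$source == b & e$target == a))))
}
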