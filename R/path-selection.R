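#' Create a selected path
#'
#' An ordered, repetition-free sequence of node ids over a pathway graph.
#' Consecutive nodes must be connected by a graph edge (respecting
#' direction; undirected edges count both ways) or by a user-forced edge.
#'
#' @param graph A [pathway_graph()].
#' @param nodes Character vector of node ids (length >= 1).
#' @param forced_edges Two-column character matrix (source, target) of
#'   consecutive pairs that are not graph edges.
#' @return An object of class `selected_path`.
#' @export
selected_path <- function(graph, nodes, forced_edges = NULL) {
  nodes <- as.character(nodes)
  if (!length(nodes)) stop("a path needs at least one node")
  missing <- setdiff(nodes, names(graph$nodes))
  if (length(missing)) stop("unknown nodes: ", paste(missing, collapse = ", "))
  if (anyDuplicated(nodes)) stop("path repeats a node (simple paths only)")
  if (is.null(forced_edges))
    forced_edges <- matrix(character(), ncol = 2,
                           dimnames = list(NULL, c("source", "target")))
  p <- structure(list(graph_ref = graph$pathway_id, nodes = nodes,
                      forced_edges = forced_edges),
                 class = "selected_path")
  validate_path_connectivity(graph, p)
  p
}

validate_path_connectivity <- function(graph, path) {
  n <- path$nodes
  if (length(n) < 2) return(invisible(TRUE))
  for (i in seq_len(length(n) - 1)) {
    a <- n[i]; b <- n[i + 1]
    if (!has_edge(graph, a, b) && !is_forced(path, a, b))
      stop("consecutive nodes ", a, " -> ", b,
           " are neither connected nor forced")
  }
  invisible(TRUE)
}

is_forced <- function(path, a, b) {
  fe <- path$forced_edges
  nrow(fe) > 0 && any(fe[, 1] == a & fe[, 2] == b)
}

#' @export
print.selected_path <- function(x, ...) {
  cat(sprintf("selected_path on '%s': %s", x$graph_ref,
              paste(x$nodes, collapse = " -> ")))
  if (nrow(x$forced_edges))
    cat(sprintf("  [%d forced edge(s)]", nrow(x$forced_edges)))
  cat("\n")
  invisible(x)
}

#' Extend a path at either end
#'
#' The iterative selection mode: grow the path one adjacent node at a time,
#' in either direction. At the tail the new node must be a successor of the
#' terminal node; at the head, a predecessor of the first node (undirected
#' edges qualify either way).
#'
#' @param graph A [pathway_graph()].
#' @param path A [selected_path()].
#' @param node_id Node to add.
#' @param end `"tail"` (append) or `"head"` (prepend).
#' @return A new `selected_path`; the input is unchanged.
#' @export
extend_path <- function(graph, path, node_id, end = c("tail", "head")) {
  end <- match.arg(end)
  if (!node_id %in% names(graph$nodes)) stop("unknown node: ", node_id)
  if (node_id %in% path$nodes)
    stop("node ", node_id, " already in path: would create cycle")
  anchor <- if (end == "tail") path$nodes[length(path$nodes)] else path$nodes[1]
  ok <- if (end == "tail") has_edge(graph, anchor, node_id)
        else has_edge(graph, node_id, anchor)
  if (!ok) stop("node ", node_id, " is not connected to ", anchor,
                " in that direction")
  path$nodes <- if (end == "tail") c(path$nodes, node_id)
                else c(node_id, path$nodes)
  path
}

#' Force an edge while extending a path
#'
#' The force mode: extend the path by a node that is not adjacent in the
#' pathway, recording the injected pair in `forced_edges` so it can be
#' rendered distinctly (dashed). Forcing a pair that does exist as a graph
#' edge behaves exactly like [extend_path()] and records nothing.
#'
#' @inheritParams extend_path
#' @return A new `selected_path` with the pair in `forced_edges` when the
#'   graph lacks the edge.
#' @export
force_edge <- function(graph, path, node_id, end = c("tail", "head")) {
  end <- match.arg(end)
  if (!node_id %in% names(graph$nodes)) stop("unknown node: ", node_id)
  if (node_id %in% path$nodes)
    stop("node ", node_id, " already in path: would create cycle")
  anchor <- if (end == "tail") path$nodes[length(path$nodes)] else path$nodes[1]
  pair <- if (end == "tail") c(anchor, node_id) else c(node_id, anchor)
  exists <- has_edge(graph, pair[1], pair[2])
  path$nodes <- if (end == "tail") c(path$nodes, node_id)
                else c(node_id, path$nodes)
  if (!exists)
    path$forced_edges <- rbind(path$forced_edges, matrix(pair, ncol = 2))
  path
}

#' Enumerate alternative paths between two nodes
#'
#' Bounded enumeration of all simple directed paths from `start` to `end`
#' (undirected edges traversable both ways), sorted by length and then
#' lexicographically by node-id sequence, so the first entry is a shortest
#' path and the ordering is independent of edge insertion order. When more
#' than `max_paths` paths exist the list is truncated and flagged.
#'
#' @param graph A [pathway_graph()].
#' @param start,end Distinct node ids.
#' @param max_len Maximum path length in edges.
#' @param max_paths Maximum number of alternatives kept.
#' @return An object of class `path_alternatives` with fields `start`,
#'   `end`, `paths` (list of [selected_path()]), `selected` (1-based index),
#'   `status` (`"ok"` or `"no_path"`) and `truncated`.
#' @export
find_alternatives <- function(graph, start, end, max_len = 20, max_paths = 64) {
  if (!start %in% names(graph$nodes)) stop("unknown node: ", start)
  if (!end %in% names(graph$nodes)) stop("unknown node: ", end)
  if (identical(start, end)) stop("start and end must differ")

  adj <- adjacency_list(graph)
  found <- list()
  truncated <- FALSE
  hard_cap <- max_paths * 8L  # enumerate past max_paths so sorting sees ties

  stack_nodes <- start
  visit <- function(cur, depth) {
    if (length(found) >= hard_cap) { truncated <<- TRUE; return() }
    if (cur == end) { found[[length(found) + 1L]] <<- stack_nodes; return() }
    if (depth >= max_len) return()
    for (nb in adj[[cur]]) {
      if (nb %in% stack_nodes) next
      stack_nodes <<- c(stack_nodes, nb)
      visit(nb, depth + 1L)
      stack_nodes <<- stack_nodes[-length(stack_nodes)]
    }
  }
  visit(start, 0L)

  # under truncation DFS order gives no length guarantee; make sure a
  # shortest path is always present before sorting
  if (truncated) {
    sp <- bfs_shortest(adj, start, end)
    if (!is.null(sp) &&
        !any(vapply(found, identical, logical(1), y = sp)))
      found[[length(found) + 1L]] <- sp
  }

  if (length(found)) {
    lens <- lengths(found)
    keys <- vapply(found, paste, character(1), collapse = "\x01")
    found <- found[order(lens, keys)]
    if (length(found) > max_paths) {
      found <- found[seq_len(max_paths)]
      truncated <- TRUE
    }
  }
  structure(list(start = start, end = end,
                 paths = lapply(found, function(n) selected_path(graph, n)),
                 selected = if (length(found)) 1L else 0L,
                 status = if (length(found)) "ok" else "no_path",
                 truncated = truncated),
            class = "path_alternatives")
}

bfs_shortest <- function(adj, start, end) {
  prev <- stats::setNames(rep(NA_character_, length(adj)), names(adj))
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- character()
    for (cur in frontier) for (nb in adj[[cur]]) {
      if (nb %in% seen) next
      prev[nb] <- cur
      if (nb == end) {
        out <- nb
        while (out[1] != start) out <- c(prev[[out[1]]], out)
        return(out)
      }
      seen <- c(seen, nb)
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  NULL
}

# successor lists keyed by node id, neighbor ids sorted
adjacency_list <- function(graph) {
  ids <- names(graph$nodes)
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) adj[[id]] <- character()
  e <- graph$edges
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    adj[[e$source[i]]] <- c(adj[[e$source[i]]], e$target[i])
    if (!e$directed[i]) adj[[e$target[i]]] <- c(adj[[e$target[i]]], e$source[i])
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' @export
print.path_alternatives <- function(x, ...) {
  cat(sprintf("path_alternatives %s -> %s: %d path(s)%s [%s]\n",
              x$start, x$end, length(x$paths),
              if (x$truncated) " (truncated)" else "", x$status))
  for (i in seq_along(x$paths))
    cat(sprintf("  %s[%d] %s\n", if (i == x$selected) "*" else " ", i,
                paste(x$paths[[i]]$nodes, collapse = " -> ")))
  invisible(x)
}

#' Select one of the enumerated alternatives
#'
#' @param alts A `path_alternatives` object.
#' @param index 1-based index into `alts$paths`.
#' @return The updated `path_alternatives`.
#' @export
select_alternative <- function(alts, index) {
  index <- as.integer(index)
  if (!length(alts$paths)) stop("no paths to select from")
  if (index < 1L || index > length(alts$paths))
    stop("index out of range [1, ", length(alts$paths), "]")
  alts$selected <- index
  alts
}

#' Step cyclically through alternatives
#'
#' Mirrors scroll-wheel switching between highlighted alternatives:
#' stepping past the last path wraps to the first.
#'
#' @param alts A `path_alternatives` object.
#' @param direction `"next"` or `"prev"`.
#' @return The updated `path_alternatives`.
#' @export
step_alternative <- function(alts, direction = c("next", "prev")) {
  direction <- match.arg(direction)
  k <- length(alts$paths)
  if (!k) stop("no paths to step through")
  delta <- if (direction == "next") 1L else -1L
  alts$selected <- ((alts$selected - 1L + delta) %% k) + 1L
  alts
}

#' Currently selected path of an alternatives set
#' @param alts A `path_alternatives` object.
#' @return A [selected_path()].
#' @export
current_path <- function(alts) {
  if (!length(alts$paths)) stop("no path available (status: ", alts$status, ")")
  alts$paths[[alts$selected]]
}

#' Preview possible one-step extensions of a path
#'
#' Lists the immediate candidates for growing the path: predecessors of the
#' first node (head side) and successors of the terminal node (tail side)
#' that are not already on the path, in deterministic (node id) order.
#'
#' @param graph A [pathway_graph()].
#' @param path A [selected_path()].
#' @return List with `head` and `tail` data frames as from [neighbors()].
#' @export
preview_extensions <- function(graph, path) {
  first <- path$nodes[1]; last <- path$nodes[length(path$nodes)]
  head_nb <- neighbors(graph, first, "in")
  tail_nb <- neighbors(graph, last, "out")
  list(head = head_nb[!head_nb$node %in% path$nodes, , drop = FALSE],
       tail = tail_nb[!tail_nb$node %in% path$nodes, , drop = FALSE])
}
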