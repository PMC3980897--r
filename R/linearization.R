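#' Compute joining and leaving branches along a path
#'
#' For each node of the extracted path, off-path in-neighbors form at most
#' one joining branch group and off-path out-neighbors at most one leaving
#' branch group (the path's own predecessor/successor never counts as a
#' branch). Each group records the first node of every branch ("head"),
#' ordered by node label then id so the linear view is reproducible.
#'
#' @param graph A [pathway_graph()].
#' @param path A [selected_path()].
#' @return An object of class `linear_path_spec` with fields `path`,
#'   `branches` (list of branch records: `anchor`, `direction`, `heads`,
#'   `expanded`) and `order` (node ids top-down, equal to the path order).
#' @export
compute_branches <- function(graph, path) {
  branches <- list()
  for (nid in path$nodes) {
    inn <- neighbors(graph, nid, "in")
    out <- neighbors(graph, nid, "out")
    joining <- setdiff(unique(inn$node), path$nodes)
    leaving <- setdiff(unique(out$node), path$nodes)
    if (length(joining))
      branches[[length(branches) + 1L]] <- list(
        anchor = nid, direction = "joining",
        heads = order_heads(graph, joining), expanded = FALSE)
    if (length(leaving))
      branches[[length(branches) + 1L]] <- list(
        anchor = nid, direction = "leaving",
        heads = order_heads(graph, leaving), expanded = FALSE)
  }
  structure(list(path = path, branches = branches, order = path$nodes),
            class = "linear_path_spec")
}

order_heads <- function(graph, ids) {
  labels <- vapply(graph$nodes[ids], function(n) n$label, character(1))
  ids[order(labels, ids)]
}

#' @export
print.linear_path_spec <- function(x, ...) {
  cat(sprintf("linear_path_spec: %d node(s), %d branch group(s)\n",
              length(x$order), length(x$branches)))
  for (b in x$branches)
    cat(sprintf("  %s @%s: %d head(s)%s\n", b$direction, b$anchor,
                length(b$heads), if (b$expanded) " [expanded]" else ""))
  invisible(x)
}

#' Switch the extracted path onto a branch
#'
#' Selecting a leaving branch at `anchor` discards all path nodes below the
#' anchor and follows the branch from `head` onward: nodes are appended as
#' long as the current node has exactly one eligible continuation (a
#' successor not yet on the path); the walk stops at a dead end or where a
#' new branch opens (two or more continuations). A joining branch works
#' symmetrically, walking backwards over predecessors and replacing the
#' segment above the anchor. Forced edges outside the retained segment are
#' discarded.
#'
#' @param graph A [pathway_graph()].
#' @param path A [selected_path()].
#' @param anchor Path node where the branching occurs.
#' @param head First node of the chosen branch.
#' @param direction `"leaving"` or `"joining"`.
#' @return A new [selected_path()].
#' @export
switch_branch <- function(graph, path, anchor, head,
                          direction = c("leaving", "joining")) {
  direction <- match.arg(direction)
  spec <- compute_branches(graph, path)
  match_ok <- any(vapply(spec$branches, function(b)
    b$anchor == anchor && b$direction == direction && head %in% b$heads,
    logical(1)))
  if (!match_ok)
    stop("(", anchor, ", ", head, ", ", direction, ") is not a branch of this path")

  ai <- match(anchor, path$nodes)
  kept <- if (direction == "leaving") path$nodes[seq_len(ai)]
          else path$nodes[ai:length(path$nodes)]

  walk <- head
  repeat {
    cur <- walk[length(walk)]
    nb <- if (direction == "leaving") neighbors(graph, cur, "out")
          else neighbors(graph, cur, "in")
    elig <- setdiff(unique(nb$node), c(kept, walk))
    if (length(elig) != 1L) break
    walk <- c(walk, elig)
  }
  new_nodes <- if (direction == "leaving") c(kept, walk)
               else c(rev(walk), kept)

  fe <- path$forced_edges
  if (nrow(fe)) {
    pairs_kept <- paste(new_nodes[-length(new_nodes)], new_nodes[-1])
    keep <- paste(fe[, 1], fe[, 2]) %in% pairs_kept
    fe <- fe[keep, , drop = FALSE]
  }
  selected_path(graph, new_nodes, fe)
}

#' Expand one abstract branch group
#'
#' Marks the group at (`anchor`, `direction`) as expanded. At most one
#' group is expanded at a time (the rendered view draws the expanded heads
#' with data previews and grays out the remaining groups), so expanding a
#' group collapses any other.
#'
#' @param spec A `linear_path_spec`.
#' @param anchor Path node of the group.
#' @param direction `"joining"` or `"leaving"`.
#' @return The updated `linear_path_spec`.
#' @export
expand_branch <- function(spec, anchor, direction = c("leaving", "joining")) {
  direction <- match.arg(direction)
  hit <- FALSE
  for (i in seq_along(spec$branches)) {
    b <- spec$branches[[i]]
    on <- b$anchor == anchor && b$direction == direction
    spec$branches[[i]]$expanded <- on
    hit <- hit || on
  }
  if (!hit) stop("no ", direction, " branch group at node ", anchor)
  spec
}

#' Collapse all branch groups
#' @param spec A `linear_path_spec`.
#' @return The updated `linear_path_spec` with every group collapsed.
#' @export
collapse_branches <- function(spec) {
  for (i in seq_along(spec$branches)) spec$branches[[i]]$expanded <- FALSE
  spec
}
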