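# Rectangles are c(x0, y0, x1, y1) in image coordinates (y down).

node_rect <- function(node, inflate = 0) {
  b <- node$bbox
  c(b[1] - b[3] / 2 - inflate, b[2] - b[4] / 2 - inflate,
    b[1] + b[3] / 2 + inflate, b[2] + b[4] / 2 + inflate)
}

rects_overlap <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

#' Does a segment intersect an axis-aligned rectangle?
#'
#' Closed test: touching the rectangle boundary counts as intersecting.
#'
#' @param p,q Segment endpoints, numeric `c(x, y)`.
#' @param rect Numeric `c(x0, y0, x1, y1)`.
#' @return Logical scalar.
#' @export
seg_intersects_rect <- function(p, q, rect) {
  t0 <- 0; t1 <- 1
  for (axis in 1:2) {
    d <- q[axis] - p[axis]
    lo <- rect[axis]; hi <- rect[axis + 2]
    if (d == 0) {
      if (p[axis] < lo || p[axis] > hi) return(FALSE)
    } else {
      ta <- (lo - p[axis]) / d; tb <- (hi - p[axis]) / d
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

#' Is a point inside a closed polygon ring?
#'
#' Even-odd ray casting; points on the boundary may report either side.
#'
#' @param pt Numeric `c(x, y)`.
#' @param ring Two-column matrix of vertices (closing edge implied).
#' @return Logical scalar.
#' @export
point_in_ring <- function(pt, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- ring[i, 2]; yj <- ring[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xint <- ring[j, 1] + (pt[2] - yj) / (yi - yj) * (ring[i, 1] - ring[j, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

polyline_intersects_rect <- function(poly, rect) {
  for (i in seq_len(nrow(poly) - 1))
    if (seg_intersects_rect(poly[i, ], poly[i + 1, ], rect)) return(TRUE)
  FALSE
}

ring_intersects_rect <- function(ring, rect) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  if (polyline_intersects_rect(closed, rect)) return(TRUE)
  # rectangle entirely inside the ring
  point_in_ring(c((rect[1] + rect[3]) / 2, (rect[2] + rect[4]) / 2), ring)
}

#' Route an edge of the path highlight around obstacles
#'
#' Returns the polyline connecting the centers of nodes `a` and `b`. If the
#' straight segment clears the bounding boxes of all nodes off the path
#' (inflated by `margin`; touching at exactly the margin counts as
#' blocked), it is used directly. Otherwise an orthogonal detour is
#' searched on a lattice spanned by the endpoint and obstacle coordinates,
#' and the shortest detour whose segments keep at least `margin` clearance
#' from every off-path box is returned. With `orthogonal = TRUE` a clear
#' but diagonal segment is also replaced by an orthogonal route (used for
#' the rectilinear corridor geometry). If no clear route exists the
#' straight segment is returned with a warning.
#'
#' @param graph A [pathway_graph()].
#' @param a,b Node ids to connect.
#' @param path_nodes Node ids on the selected path (never obstacles).
#' @param margin Clearance in pixels.
#' @param orthogonal Force an axis-parallel polyline.
#' @return Two-column matrix of polyline vertices.
#' @export
route_edge <- function(graph, a, b, path_nodes, margin = 6, orthogonal = FALSE) {
  ca <- graph$nodes[[a]]$bbox[1:2]
  cb <- graph$nodes[[b]]$bbox[1:2]
  names(ca) <- names(cb) <- NULL
  obstacle_ids <- setdiff(names(graph$nodes), unique(c(path_nodes, a, b)))
  obs <- lapply(graph$nodes[obstacle_ids], node_rect, inflate = margin)

  straight <- rbind(ca, cb)
  rownames(straight) <- NULL
  blocked <- any(vapply(obs, function(r) seg_intersects_rect(ca, cb, r),
                        logical(1)))
  axis_aligned <- ca[1] == cb[1] || ca[2] == cb[2]
  if (!blocked && (!orthogonal || axis_aligned)) return(straight)

  # restrict the lattice to obstacles near the span of the two endpoints
  pad <- 4 * margin + 40
  region <- c(min(ca[1], cb[1]) - pad, min(ca[2], cb[2]) - pad,
              max(ca[1], cb[1]) + pad, max(ca[2], cb[2]) + pad)
  near <- obs[vapply(obs, rects_overlap, logical(1), b = region)]
  xs <- sort(unique(c(ca[1], cb[1],
                      unlist(lapply(near, function(r) c(r[1] - margin, r[3] + margin))))))
  ys <- sort(unique(c(ca[2], cb[2],
                      unlist(lapply(near, function(r) c(r[2] - margin, r[4] + margin))))))
  route <- lattice_route(ca, cb, xs, ys, near)
  if (is.null(route)) {
    warning("no clear route between ", a, " and ", b,
            "; falling back to straight segment")
    return(straight)
  }
  route
}

# Dijkstra over the orthogonal lattice xs x ys; segments must clear `obs`.
lattice_route <- function(ca, cb, xs, ys, obs) {
  nx <- length(xs); ny <- length(ys)
  idx <- function(i, j) (i - 1L) * ny + j
  n <- nx * ny
  px <- rep(xs, each = ny); py <- rep(ys, times = nx)
  start <- idx(match(ca[1], xs), match(ca[2], ys))
  goal <- idx(match(cb[1], xs), match(cb[2], ys))

  seg_ok <- function(k1, k2) {
    p <- c(px[k1], py[k1]); q <- c(px[k2], py[k2])
    for (r in obs) if (seg_intersects_rect(p, q, r)) return(FALSE)
    TRUE
  }
  dist <- rep(Inf, n); dist[start] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    masked <- dist
    masked[done] <- Inf
    u <- which.min(masked)
    if (!is.finite(masked[u])) return(NULL)
    if (u == goal) break
    done[u] <- TRUE
    i <- (u - 1L) %/% ny + 1L; j <- (u - 1L) %% ny + 1L
    nbrs <- c(if (i > 1L) idx(i - 1L, j), if (i < nx) idx(i + 1L, j),
              if (j > 1L) idx(i, j - 1L), if (j < ny) idx(i, j + 1L))
    for (v in nbrs) {
      if (done[v]) next
      w <- abs(px[u] - px[v]) + abs(py[u] - py[v])
      if (dist[u] + w < dist[v] && seg_ok(u, v)) {
        dist[v] <- dist[u] + w
        prev[v] <- u
      }
    }
  }
  path <- goal
  while (path[1] != start) path <- c(prev[path[1]], path)
  pts <- cbind(px[path], py[path])
  simplify_collinear(pts)
}

simplify_collinear <- function(pts) {
  if (nrow(pts) <= 2) return(pts)
  keep <- c(TRUE, vapply(2:(nrow(pts) - 1), function(i) {
    v1 <- pts[i, ] - pts[i - 1, ]; v2 <- pts[i + 1, ] - pts[i, ]
    v1[1] * v2[2] - v1[2] * v2[1] != 0
  }, logical(1)), TRUE)
  pts[keep, , drop = FALSE]
}

#' Corridor geometry wrapping a selected path
#'
#' Builds the continuous highlight region around a path: the union of the
#' member bounding boxes inflated by `radius` and of rectangular strokes of
#' half-width `radius` along orthogonally routed edges between consecutive
#' path nodes (forced pairs included). Edge routes are computed with
#' clearance `radius + margin`, so the stroke sides keep at least `margin`
#' distance from every off-path node box. The exact member boxes are
#' reported as holes so that, rendered with the even-odd fill rule, node
#' interiors stay unobscured.
#'
#' @param graph A [pathway_graph()].
#' @param path A [selected_path()].
#' @param radius Corridor half-width in pixels.
#' @param margin Extra clearance from off-path nodes in pixels.
#' @return An object of class `corridor_geometry`: `outline` (list of
#'   closed rings, two-column matrices), `holes` (member boxes as rings),
#'   `routes` (edge polylines) and `boxes` (inflated member rectangles).
#' @export
corridor <- function(graph, path, radius = 12, margin = 6) {
  nodes <- path$nodes
  member_rects <- lapply(graph$nodes[nodes], node_rect, inflate = radius)
  routes <- list()
  if (length(nodes) > 1) {
    for (i in seq_len(length(nodes) - 1)) {
      routes[[i]] <- route_edge(graph, nodes[i], nodes[i + 1], nodes,
                                margin = radius + margin, orthogonal = TRUE)
    }
  }
  stroke_rects <- list()
  for (poly in routes) {
    for (i in seq_len(nrow(poly) - 1)) {
      p <- poly[i, ]; q <- poly[i + 1, ]
      stroke_rects[[length(stroke_rects) + 1L]] <-
        c(min(p[1], q[1]) - radius, min(p[2], q[2]) - radius,
          max(p[1], q[1]) + radius, max(p[2], q[2]) + radius)
    }
  }
  rects <- c(member_rects, stroke_rects)
  outline <- rect_union_rings(rects)
  holes <- lapply(graph$nodes[nodes], function(n) {
    r <- node_rect(n)
    rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4]))
  })
  structure(list(outline = outline, holes = unname(holes),
                 routes = routes, boxes = unname(member_rects)),
            class = "corridor_geometry")
}

# Boundary rings of the union of axis-aligned rectangles, via coordinate
# compression and grid-cell boundary tracing. Ring vertices are exact input
# coordinates.
rect_union_rings <- function(rects) {
  if (!length(rects)) return(list())
  xs <- sort(unique(unlist(lapply(rects, function(r) c(r[1], r[3])))))
  ys <- sort(unique(unlist(lapply(rects, function(r) c(r[2], r[4])))))
  nx <- length(xs) - 1L; ny <- length(ys) - 1L
  covered <- matrix(FALSE, nx, ny)
  for (r in rects) {
    i0 <- match(r[1], xs); i1 <- match(r[3], xs) - 1L
    j0 <- match(r[2], ys); j1 <- match(r[4], ys) - 1L
    if (i1 >= i0 && j1 >= j0) covered[i0:i1, j0:j1] <- TRUE
  }
  cov <- function(i, j) i >= 1L && i <= nx && j >= 1L && j <= ny && covered[i, j]

  # directed boundary edges (interior kept on a consistent side), keyed by
  # lattice indices; convention checked to close clockwise in y-down coords
  from <- list(); to <- list()
  add <- function(p, q) { from[[length(from) + 1L]] <<- p; to[[length(to) + 1L]] <<- q }
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!covered[i, j]) next
    if (!cov(i, j - 1L)) add(c(i + 1L, j), c(i, j))          # top: right->left
    if (!cov(i, j + 1L)) add(c(i, j + 1L), c(i + 1L, j + 1L)) # bottom: left->right
    if (!cov(i - 1L, j)) add(c(i, j), c(i, j + 1L))          # left: down
    if (!cov(i + 1L, j)) add(c(i + 1L, j + 1L), c(i + 1L, j)) # right: up
  }
  if (!length(from)) return(list())
  key <- function(p) paste(p[1], p[2])
  m <- length(from)
  used <- rep(FALSE, m)
  out_at <- split(seq_len(m), vapply(from, key, character(1)))
  rings <- list()
  for (s in seq_len(m)) {
    if (used[s]) next
    ring_idx <- integer()
    cur <- s
    repeat {
      used[cur] <- TRUE
      ring_idx <- c(ring_idx, cur)
      nxt_candidates <- out_at[[key(to[[cur]])]]
      nxt_candidates <- nxt_candidates[!used[nxt_candidates]]
      if (!length(nxt_candidates)) break
      if (length(nxt_candidates) > 1L) {
        # saddle vertex: prefer the sharpest left turn to keep rings simple
        d_in <- to[[cur]] - from[[cur]]
        turn <- vapply(nxt_candidates, function(e) {
          d_out <- to[[e]] - from[[e]]
          d_in[1] * d_out[2] - d_in[2] * d_out[1]
        }, numeric(1))
        nxt_candidates <- nxt_candidates[order(-turn)]
      }
      cur <- nxt_candidates[1]
    }
    pts <- do.call(rbind, from[ring_idx])
    pts <- cbind(xs[pts[, 1]], ys[pts[, 2]])
    pts <- simplify_ring(pts)
    if (nrow(pts) >= 4) rings[[length(rings) + 1L]] <- pts
  }
  rings
}

simplify_ring <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  keep <- vapply(seq_len(n), function(i) {
    prv <- pts[(i - 2) %% n + 1, ]; cur <- pts[i, ]; nxt <- pts[i %% n + 1, ]
    v1 <- cur - prv; v2 <- nxt - cur
    v1[1] * v2[2] - v1[2] * v2[1] != 0
  }, logical(1))
  pts[keep, , drop = FALSE]
}
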