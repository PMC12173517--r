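#' Build a dendritic river network from an edge table
#'
#' A river network is represented as a rooted tree: edges are stored
#' upstream -> downstream and every node except the single outlet has
#' exactly one downstream edge, so that each point of the network has a
#' unique route to the outlet. This rooted representation is what makes
#' flow-connectedness between two points well defined.
#'
#' @param edges data.frame with columns `edge_id`, `up_node`, `down_node`,
#'   `length_m` (positive, metres). `length_m` may be omitted when `nodes`
#'   carries coordinates, in which case lengths are the straight-line
#'   distances between the edge endpoints.
#' @param nodes optional data.frame with columns `node_id`, `x`, `y`
#'   (planar metres). When omitted, nodes are created without coordinates
#'   and Euclidean site distances are unavailable.
#' @param outlet optional outlet node id. When given and the stored
#'   orientation does not already drain to it, edges are re-oriented so all
#'   paths lead to this outlet. When omitted the outlet is inferred as the
#'   unique node with no downstream edge.
#'
#' @return An object of class `river_network`: a list with `nodes`
#'   (data.frame: node_id, x, y), `edges` (data.frame: edge_id, up_node,
#'   down_node, length_m), `outlet`, and rooted-tree indices (`parent_edge`,
#'   `parent_node`, `depth_m` = watercourse distance from each node to the
#'   outlet).
#'
#' @details Braided channels, multiple components and cycles are rejected:
#'   every computation downstream (watercourse distance, flow-connectedness,
#'   fragment assignment) assumes the route between any two points is unique.
#'
#' @examples
#' eds <- data.frame(edge_id = 1:3,
#'                   up_node = c("b1", "b2", "c"),
#'                   down_node = c("c", "c", "out"),
#'                   length_m = c(100, 200, 300))
#' net <- build_network(eds)
#' net$outlet
#' @export
build_network <- function(edges, nodes = NULL, outlet = NULL) {
  edges <- as.data.frame(edges)
  req <- c("edge_id", "up_node", "down_node")
  if (!all(req %in% names(edges)))
    stop("edge table must have columns edge_id, up_node, down_node")
  edges$up_node <- as.character(edges$up_node)
  edges$down_node <- as.character(edges$down_node)
  if (anyDuplicated(edges$edge_id))
    stop("duplicated edge_id in edge table")

  node_ids <- unique(c(edges$up_node, edges$down_node))
  if (is.null(nodes)) {
    nodes <- data.frame(node_id = node_ids, x = NA_real_, y = NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes)
    nodes$node_id <- as.character(nodes$node_id)
    if (!all(node_ids %in% nodes$node_id))
      stop("edge table references node ids missing from the node table")
    nodes <- nodes[match(node_ids, nodes$node_id), , drop = FALSE]
    rownames(nodes) <- NULL
  }

  if (!("length_m" %in% names(edges)) || all(is.na(edges$length_m))) {
    if (all(is.na(nodes$x)))
      stop("edge lengths missing and no node coordinates to derive them")
    iu <- match(edges$up_node, nodes$node_id)
    id <- match(edges$down_node, nodes$node_id)
    edges$length_m <- sqrt((nodes$x[iu] - nodes$x[id])^2 +
                           (nodes$y[iu] - nodes$y[id])^2)
  }
  if (any(!is.finite(edges$length_m)) || any(edges$length_m <= 0))
    stop("all edge lengths must be finite and > 0")

  n_nodes <- length(node_ids)
  if (nrow(edges) != n_nodes - 1L)
    stop(sprintf(
      "not a tree: %d edges for %d nodes (a cycle or disconnected component)",
      nrow(edges), n_nodes))

  ## undirected adjacency; confirms single component & acyclicity together
  ## with the edge-count check above
  adj <- vector("list", n_nodes)
  names(adj) <- node_ids
  for (k in seq_len(nrow(edges))) {
    u <- edges$up_node[k]; d <- edges$down_node[k]
    adj[[u]] <- c(adj[[u]], k)
    adj[[d]] <- c(adj[[d]], k)
  }

  if (is.null(outlet)) {
    cand <- setdiff(node_ids, edges$up_node)
    if (length(cand) != 1L)
      stop(sprintf("cannot infer outlet: %d candidate nodes lack a downstream edge",
                   length(cand)))
    out_going <- table(edges$up_node)
    if (any(out_going > 1L))
      stop("a node has more than one downstream edge; pass `outlet` to re-orient")
    outlet <- cand
  } else {
    outlet <- as.character(outlet)
    if (!outlet %in% node_ids) stop("declared outlet is not a node of the network")
  }

  ## root at the outlet by BFS over the undirected tree, re-orienting edges
  parent_edge <- rep(NA_integer_, n_nodes)   # edge row carrying node downstream
  parent_node <- rep(NA_character_, n_nodes)
  depth_m <- rep(NA_real_, n_nodes)
  names(parent_edge) <- names(parent_node) <- names(depth_m) <- node_ids
  depth_m[outlet] <- 0
  queue <- outlet
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (k in adj[[v]]) {
      u <- edges$up_node[k]; d <- edges$down_node[k]
      w <- if (u == v) d else u
      if (!is.na(depth_m[w])) next
      if (edges$down_node[k] != v) {       # flip to drain towards outlet
        edges$up_node[k] <- w
        edges$down_node[k] <- v
      }
      parent_edge[w] <- k
      parent_node[w] <- v
      depth_m[w] <- depth_m[v] + edges$length_m[k]
      queue <- c(queue, w)
    }
  }
  if (anyNA(depth_m))
    stop("network is not connected (multiple components)")

  ## all-pairs node distances (BFS from every node); networks here are
  ## catchment-sized so the V^2 table is cheap and makes every pairwise
  ## point computation a lookup
  node_dist <- matrix(0, n_nodes, n_nodes, dimnames = list(node_ids, node_ids))
  for (s in seq_len(n_nodes)) {
    dd <- rep(NA_real_, n_nodes); names(dd) <- node_ids
    dd[s] <- 0; queue <- node_ids[s]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in adj[[v]]) {
        u <- edges$up_node[k]; d <- edges$down_node[k]
        w <- if (u == v) d else u
        if (!is.na(dd[w])) next
        dd[w] <- dd[v] + edges$length_m[k]
        queue <- c(queue, w)
      }
    }
    node_dist[s, ] <- dd
  }

  net <- list(nodes = nodes, edges = edges, outlet = outlet,
              parent_edge = parent_edge, parent_node = parent_node,
              depth_m = depth_m, node_dist = node_dist)
  class(net) <- "river_network"
  net
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf("river_network: %d nodes, %d edges, outlet '%s', total length %.1f km\n",
              nrow(x$nodes), nrow(x$edges), x$outlet,
              sum(x$edges$length_m) / 1000))
  invisible(x)
}

#' @export
plot.river_network <- function(x, sites = NULL, barriers = NULL, ...) {
  if (all(is.na(x$nodes$x))) stop("network has no coordinates to plot")
  iu <- match(x$edges$up_node, x$nodes$node_id)
  id <- match(x$edges$down_node, x$nodes$node_id)
  graphics::plot(x$nodes$x, x$nodes$y, type = "n", asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  graphics::segments(x$nodes$x[iu], x$nodes$y[iu],
                     x$nodes$x[id], x$nodes$y[id], col = "steelblue")
  if (!is.null(sites)) {
    xy <- placement_coords(sites, x)
    graphics::points(xy$x, xy$y, pch = 19, col = "darkgreen", cex = 0.8)
  }
  if (!is.null(barriers)) {
    xy <- placement_coords(barriers, x)
    graphics::points(xy$x, xy$y, pch = 17, col = "black")
  }
  invisible(x)
}

## node watercourse distance: precomputed all-pairs table lookup
node_distance <- function(net, u, v) {
  net$node_dist[u, v]
}

#' Create validated point placements on a river network
#'
#' A placement locates an object (sampling site or barrier) on an edge of the
#' network by its offset in metres from the edge's upstream node.
#'
#' @param id character vector of object ids.
#' @param edge_id edge ids (must exist in `net`).
#' @param offset_m numeric offsets, `0 <= offset <= edge length`.
#' @param net a [build_network()] object.
#' @return data.frame of class `placements` with columns
#'   `id`, `edge_id`, `offset_m`.
#' @export
placements <- function(id, edge_id, offset_m, net) {
  stopifnot(inherits(net, "river_network"))
  k <- match(edge_id, net$edges$edge_id)
  if (anyNA(k)) stop("placement references an edge not in the network")
  len <- net$edges$length_m[k]
  if (any(offset_m < 0 | offset_m > len + 1e-9))
    stop("placement offset outside [0, edge length]")
  out <- data.frame(id = as.character(id), edge_id = edge_id,
                    offset_m = pmin(offset_m, len), stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop("duplicated placement ids")
  class(out) <- c("placements", "data.frame")
  out
}

#' Interpolated planar coordinates of placements (straight-line edges)
#' @param pl a [placements()] data.frame.
#' @param net the network the placements live on.
#' @return data.frame id, x, y.
#' @export
placement_coords <- function(pl, net) {
  k <- match(pl$edge_id, net$edges$edge_id)
  iu <- match(net$edges$up_node[k], net$nodes$node_id)
  id <- match(net$edges$down_node[k], net$nodes$node_id)
  f <- pl$offset_m / net$edges$length_m[k]
  data.frame(id = pl$id,
             x = net$nodes$x[iu] + f * (net$nodes$x[id] - net$nodes$x[iu]),
             y = net$nodes$y[iu] + f * (net$nodes$y[id] - net$nodes$y[iu]),
             stringsAsFactors = FALSE)
}

#' Snap planar points to the nearest point of the network
#'
#' Each point is perpendicularly projected onto every (straight) edge and
#' assigned to the closest projection; ties are broken by the lowest edge id,
#' which makes snapping deterministic.
#'
#' @param pts data.frame with columns `id`, `x`, `y`.
#' @param net a [build_network()] object whose nodes carry coordinates.
#' @return a [placements()] data.frame with an extra `snap_dist_m` column.
#' @export
snap_to_network <- function(pts, net) {
  if (all(is.na(net$nodes$x))) stop("network has no coordinates to snap to")
  iu <- match(net$edges$up_node, net$nodes$node_id)
  idn <- match(net$edges$down_node, net$nodes$node_id)
  x1 <- net$nodes$x[iu]; y1 <- net$nodes$y[iu]
  x2 <- net$nodes$x[idn]; y2 <- net$nodes$y[idn]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  ord <- order(net$edges$edge_id)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    t <- pmin(1, pmax(0, ((pts$x[i] - x1) * dx + (pts$y[i] - y1) * dy) / len2))
    px <- x1 + t * dx; py <- y1 + t * dy
    d2 <- (pts$x[i] - px)^2 + (pts$y[i] - py)^2
    best <- ord[which.min(d2[ord])]   # lowest edge id among ties
    list(edge = net$edges$edge_id[best],
         off = t[best] * net$edges$length_m[best],
         dist = sqrt(d2[best]))
  })
  out <- placements(pts$id,
                    unlist(lapply(res, `[[`, "edge")),
                    vapply(res, `[[`, 0, "off"), net)
  out$snap_dist_m <- vapply(res, `[[`, 0, "dist")
  out
}
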