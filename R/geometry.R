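## Pairwise geometry on a rooted dendritic network: watercourse distance,
## flow-connectedness, barriers on the route, fragment assignment.
##
## All point-to-point computations exploit that routes on a tree are unique,
## so a point c lies on the route a--b exactly when
## d(a,c) + d(c,b) = d(a,b).

point_pair_distance <- function(net, e1, o1, e2, o2) {
  if (e1 == e2) return(abs(o1 - o2))
  u1 <- net$edges$up_node[e1]; d1 <- net$edges$down_node[e1]
  u2 <- net$edges$up_node[e2]; d2 <- net$edges$down_node[e2]
  l1 <- net$edges$length_m[e1]; l2 <- net$edges$length_m[e2]
  ## the route must leave edge 1 and enter edge 2 through endpoints; the
  ## minimum over endpoint combinations is exact on a tree
  min(o1        + net$node_dist[u1, u2] + o2,
      o1        + net$node_dist[u1, d2] + (l2 - o2),
      (l1 - o1) + net$node_dist[d1, u2] + o2,
      (l1 - o1) + net$node_dist[d1, d2] + (l2 - o2))
}

## watercourse distance from a point to the outlet
point_depth <- function(net, edge_idx, offset) {
  (net$edges$length_m[edge_idx] - offset) +
    net$depth_m[net$edges$down_node[edge_idx]]
}

resolve_placement <- function(pl, id, net) {
  i <- match(id, pl$id)
  if (is.na(i)) stop(sprintf("no placement with id '%s'", id))
  list(edge = match(pl$edge_id[i], net$edges$edge_id), off = pl$offset_m[i])
}

## cross-distance matrix between two placement sets (metres)
placement_dist_matrix <- function(pa, pb, net) {
  ea <- match(pa$edge_id, net$edges$edge_id); oa <- pa$offset_m
  eb <- match(pb$edge_id, net$edges$edge_id); ob <- pb$offset_m
  out <- matrix(0, nrow(pa), nrow(pb), dimnames = list(pa$id, pb$id))
  for (i in seq_len(nrow(pa)))
    for (j in seq_len(nrow(pb)))
      out[i, j] <- point_pair_distance(net, ea[i], oa[i], eb[j], ob[j])
  out
}

#' Watercourse distance between two placed points
#'
#' Length in metres of the unique path along the network between two
#' placements, including the partial edges at both ends.
#'
#' @param pl a [placements()] data.frame holding both points.
#' @param a,b placement ids.
#' @param net the shared [build_network()] object. Points on different
#'   networks (catchments) have no watercourse route; that situation must be
#'   handled by the caller, never by returning a number.
#' @return distance in metres.
#' @export
watercourse_distance <- function(pl, a, b, net) {
  pa <- resolve_placement(pl, a, net)
  pb <- resolve_placement(pl, b, net)
  point_pair_distance(net, pa$edge, pa$off, pb$edge, pb$off)
}

#' Are two placed points flow-connected?
#'
#' Two points are flow-connected when one lies on the other's downstream
#' route to the outlet (the route between them is monotone with respect to
#' flow). A route that descends through a confluence and climbs another
#' branch is flow-unconnected.
#'
#' @inheritParams watercourse_distance
#' @return logical flag.
#' @export
flow_connected <- function(pl, a, b, net) {
  pa <- resolve_placement(pl, a, net)
  pb <- resolve_placement(pl, b, net)
  da <- point_depth(net, pa$edge, pa$off)
  db <- point_depth(net, pb$edge, pb$off)
  dab <- point_pair_distance(net, pa$edge, pa$off, pb$edge, pb$off)
  tol <- 1e-6 * max(1, da, db)
  abs(da - (db + dab)) < tol || abs(db - (da + dab)) < tol
}

#' Count barriers on the open route between two points
#'
#' A barrier counts when it lies strictly between the two points along the
#' watercourse: a barrier coincident with either endpoint's own placement
#' does not separate that point from its side.
#'
#' @inheritParams watercourse_distance
#' @param barriers a [placements()] data.frame of barrier locations
#'   (already filtered of removed barriers).
#' @return integer count of barriers on the open route.
#' @export
route_barriers <- function(pl, a, b, barriers, net) {
  if (nrow(barriers) == 0L) return(0L)
  pa <- resolve_placement(pl, a, net)
  pb <- resolve_placement(pl, b, net)
  dab <- point_pair_distance(net, pa$edge, pa$off, pb$edge, pb$off)
  ke <- match(barriers$edge_id, net$edges$edge_id)
  eps <- 1e-6
  n <- 0L
  for (i in seq_len(nrow(barriers))) {
    dac <- point_pair_distance(net, pa$edge, pa$off, ke[i],
                               barriers$offset_m[i])
    dcb <- point_pair_distance(net, ke[i], barriers$offset_m[i],
                               pb$edge, pb$off)
    on_route <- abs(dac + dcb - dab) < eps * max(1, dab)
    if (on_route && dac > eps && dcb > eps) n <- n + 1L
  }
  n
}

## shared geometry core: site-site distances, site depths, barrier counts
geometry_core <- function(sites, barriers, net) {
  D <- placement_dist_matrix(sites, sites, net)
  es <- match(sites$edge_id, net$edges$edge_id)
  depth <- vapply(seq_len(nrow(sites)),
                  function(i) point_depth(net, es[i], sites$offset_m[i]), 0)
  n <- nrow(sites)
  nb <- matrix(0L, n, n, dimnames = list(sites$id, sites$id))
  if (nrow(barriers) > 0L && n > 1L) {
    BD <- placement_dist_matrix(barriers, sites, net)  # B x n
    eps <- 1e-6
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        between <- abs(BD[, i] + BD[, j] - D[i, j]) < eps * max(1, D[i, j]) &
          BD[, i] > eps & BD[, j] > eps
        nb[i, j] <- nb[j, i] <- sum(between)
      }
    }
  }
  list(D = D, depth = depth, nb = nb)
}

## connected components of the "zero barriers between" site graph,
## labelled by smallest member site id
fragments_from_nb <- function(site_ids, nb) {
  n <- length(site_ids)
  comp <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (comp[i] != comp[j] && nb[i, j] == 0L)
          comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  vapply(comp, function(cc) min(site_ids[comp == cc]), "")
}

#' Cluster sites into fragments separated by barriers
#'
#' Builds the site graph with an edge wherever the route between two sites
#' crosses no barrier, and takes connected components. Two sites share a
#' fragment exactly when their route crosses zero barriers. Fragment labels
#' are deterministic: each fragment is named after its smallest member site
#' id, so the result does not depend on site enumeration order.
#'
#' @param sites,barriers [placements()] data.frames.
#' @param net the [build_network()] object.
#' @param catchment optional catchment id recorded on the output.
#' @return data.frame of class `fragment_map`: `site`, `fragment`,
#'   `catchment`.
#' @export
assign_fragments <- function(sites, barriers, net, catchment = NA_character_) {
  core <- geometry_core(sites, barriers, net)
  out <- data.frame(site = sites$id,
                    fragment = fragments_from_nb(sites$id, core$nb),
                    catchment = catchment, stringsAsFactors = FALSE)
  class(out) <- c("fragment_map", "data.frame")
  out
}

#' Pairwise geometry table for all within-catchment site pairs
#'
#' One record per unordered site pair: watercourse distance `d_w_m`,
#' Euclidean distance `d_e_m` (from interpolated straight-line coordinates),
#' flow-connectedness, barrier-crossing flag and count, and fragment ids of
#' the two sites. With straight edges `d_e_m <= d_w_m` always holds, and
#' `barrier_crossed` is true exactly when the two sites belong to different
#' fragments.
#'
#' @inheritParams assign_fragments
#' @return data.frame with columns `site_a`, `site_b`, `d_w_m`, `d_e_m`,
#'   `flow_connected`, `barrier_crossed`, `n_barriers`, `fragment_a`,
#'   `fragment_b`, `catchment`.
#' @export
pair_geometry_table <- function(sites, barriers, net,
                                catchment = NA_character_) {
  n <- nrow(sites)
  empty <- data.frame(site_a = character(), site_b = character(),
                      d_w_m = numeric(), d_e_m = numeric(),
                      flow_connected = logical(), barrier_crossed = logical(),
                      n_barriers = integer(), fragment_a = character(),
                      fragment_b = character(), catchment = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  core <- geometry_core(sites, barriers, net)
  frag <- fragments_from_nb(sites$id, core$nb)
  has_xy <- !all(is.na(net$nodes$x))
  xy <- if (has_xy) placement_coords(sites, net) else NULL
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(i) seq(i + 1L, n)))
  dw <- core$D[cbind(ii, jj)]
  de <- if (has_xy)
    sqrt((xy$x[ii] - xy$x[jj])^2 + (xy$y[ii] - xy$y[jj])^2) else NA_real_
  tol <- 1e-6 * pmax(1, core$depth[ii], core$depth[jj])
  fc <- abs(core$depth[ii] - (core$depth[jj] + dw)) < tol |
    abs(core$depth[jj] - (core$depth[ii] + dw)) < tol
  nbv <- core$nb[cbind(ii, jj)]
  out <- data.frame(site_a = sites$id[ii], site_b = sites$id[jj],
                    d_w_m = dw, d_e_m = de, flow_connected = fc,
                    barrier_crossed = nbv > 0L, n_barriers = as.integer(nbv),
                    fragment_a = frag[ii], fragment_b = frag[jj],
                    catchment = catchment, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
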