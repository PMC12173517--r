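## Independent brute-force oracles. These deliberately avoid the package's
## own computational paths: geometry oracles subdivide the network into an
## explicit igraph and enumerate paths; the mixed-model oracle evaluates
## the restricted likelihood densely from its definition.

## subdivide the network at a set of placements and return the igraph plus
## the vertex name of each placement
oracle_graph <- function(net, pls) {
  pts <- do.call(rbind, lapply(pls, function(p)
    data.frame(id = p$id, edge_id = p$edge_id, offset_m = p$offset_m,
               stringsAsFactors = FALSE)))
  from <- character(); to <- character(); w <- numeric()
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    on_e <- pts[pts$edge_id == e$edge_id, , drop = FALSE]
    on_e <- on_e[order(on_e$offset_m), , drop = FALSE]
    chain <- c(e$up_node, on_e$id, e$down_node)
    offs <- c(0, on_e$offset_m, e$length_m)
    for (i in seq_len(length(chain) - 1L)) {
      from <- c(from, chain[i]); to <- c(to, chain[i + 1L])
      w <- c(w, offs[i + 1L] - offs[i])
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = pmax(w, 0)), directed = FALSE)
  g
}

oracle_distance <- function(g, a, b) {
  as.numeric(igraph::distances(g, a, b))
}

## a and b flow-connected <=> one lies on the other's path to the outlet
oracle_flow_connected <- function(g, a, b, outlet) {
  pa <- names(igraph::shortest_paths(g, a, outlet)$vpath[[1]])
  pb <- names(igraph::shortest_paths(g, b, outlet)$vpath[[1]])
  (b %in% pa) || (a %in% pb)
}

## count barrier vertices strictly interior to the a--b path
oracle_route_barriers <- function(g, a, b, barrier_ids) {
  path <- names(igraph::shortest_paths(g, a, b)$vpath[[1]])
  interior <- setdiff(path, c(a, b))
  sum(barrier_ids %in% interior)
}

## fragments: delete barrier vertices, components of what remains
oracle_fragments <- function(g, site_ids, barrier_ids) {
  g2 <- igraph::delete_vertices(g, intersect(barrier_ids,
                                             igraph::V(g)$name))
  comp <- igraph::components(g2)$membership
  split(site_ids, comp[site_ids])
}

## same partition? (compare set-of-sets)
same_partition <- function(a, b) {
  norm <- function(p) sort(unname(vapply(p, function(s)
    paste(sort(s), collapse = "|"), "")))
  identical(norm(a), norm(b))
}

## dense restricted / full likelihood criterion (-2 logLik) evaluated from
## the definition, for explicit variance components
dense_lmm_crit <- function(y, X, Zlist, sigma2, s2e, reml = TRUE) {
  n <- length(y); p <- ncol(X)
  V <- diag(s2e, n)
  for (i in seq_along(Zlist))
    V <- V + sigma2[i] * tcrossprod(Zlist[[i]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ld_V <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (reml) {
    ld_X <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    ld_V + ld_X + quad + (n - p) * log(2 * pi)
  } else {
    ld_V + quad + n * log(2 * pi)
  }
}

## Spearman via the rank-difference formula (average ranks)
oracle_spearman_formula <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- rep(NA_real_, m)
  run_min <- Inf
  for (k in seq_along(o)) {
    i <- o[k]
    rank_i <- m - k + 1
    run_min <- min(run_min, p[i] * m / rank_i)
    adj[i] <- min(run_min, 1)
  }
  adj
}

## lognormal series with given arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## fabricate a taylor_fit with exact parameters (portfolio oracle tests)
taylor_exact <- function(z, log_c) {
  structure(list(z = z, log_c = log_c, se_z = 0,
                 points = data.frame()), class = "taylor_fit")
}
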