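## Shared fixtures, built in code.

## Y-shaped river: two headwater branches (100 m and 200 m) meeting at a
## confluence, stem 300 m to the outlet.
y_tree <- function() {
  build_network(
    data.frame(edge_id = c("b1", "b2", "stem"),
               up_node = c("h1", "h2", "conf"),
               down_node = c("conf", "conf", "out"),
               length_m = c(100, 200, 300)),
    nodes = data.frame(node_id = c("h1", "h2", "conf", "out"),
                       x = c(-60, 120, 0, 0), y = c(380, 460, 300, 0)))
}

## small random riverscape catchment: returns list(network, sites, barriers)
random_catchment <- function(seed, n_edges = 20, n_sites = 8, n_barriers = 3) {
  cfg <- sim_config(n_catchments = 1, n_edges = n_edges, n_sites = n_sites,
                    n_barriers = n_barriers, seed = seed)
  generate_riverscape(cfg)$catchments[[1]]
}

## small pairwise dataset with known multimembership structure, for LMM
## oracle tests
tiny_mm_data <- function(seed, n = 12, n_sites = 4, n_groups = 2) {
  set.seed(seed)
  sites <- paste0("s", seq_len(n_sites))
  d <- data.frame(
    site_a = sample(sites, n, replace = TRUE),
    site_b = sample(sites, n, replace = TRUE),
    catchment = sample(paste0("c", seq_len(n_groups)), n, replace = TRUE),
    x = stats::runif(n))
  ## ensure the two members differ
  same <- d$site_a == d$site_b
  d$site_b[same] <- sites[(match(d$site_a[same], sites) %% n_sites) + 1L]
  u_s <- stats::rnorm(n_sites, 0, 0.5)
  u_c <- stats::rnorm(n_groups, 0, 0.5)
  d$y <- 0.3 + 0.8 * d$x + u_s[match(d$site_a, sites)] +
    u_s[match(d$site_b, sites)] + u_c[match(d$catchment, paste0("c", 1:n_groups))] +
    stats::rnorm(n, 0, 0.4)
  d
}
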