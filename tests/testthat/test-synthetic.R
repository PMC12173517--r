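test_that("riverscape generation is reproducible and validated", {
  cfg <- sim_config(n_catchments = 2, n_edges = 10, n_sites = 6,
                    n_barriers = 2, seed = 11)
  rs1 <- generate_riverscape(cfg)
  rs2 <- generate_riverscape(cfg)
  expect_identical(rs1$catchments[[1]]$network$edges,
                   rs2$catchments[[1]]$network$edges)
  expect_identical(rs1$catchments[[2]]$sites, rs2$catchments[[2]]$sites)
  expect_error(sim_config(n_edges = 2, n_barriers = 5), "infeasible")
  expect_error(sim_config(beta = 1.2), "lie in")
})

test_that("a single-edge riverscape yields one fragment", {
  cfg <- sim_config(n_catchments = 1, n_edges = 1, n_sites = 2,
                    n_barriers = 0, seed = 3)
  rs <- generate_riverscape(cfg)
  fm <- riverscape_fragments(rs)
  expect_equal(length(unique(fm$fragment)), 1L)
})

test_that("generated networks satisfy the tree invariants across configs", {
  for (seed in 1:20) {
    n_edges <- sample(1:30, 1)
    cfg <- sim_config(n_catchments = 1, n_edges = n_edges,
                      n_sites = 4, n_barriers = min(2, n_edges), seed = seed)
    net <- generate_riverscape(cfg)$catchments[[1]]$network
    expect_equal(nrow(net$edges), nrow(net$nodes) - 1L)
    expect_true(all(net$edges$length_m > 0))
    ## every non-outlet node has exactly one downstream edge
    tab <- table(net$edges$up_node)
    expect_true(all(tab == 1L))
    expect_false(net$outlet %in% net$edges$up_node)
    ## edge lengths equal embedded segment lengths (straight edges), so
    ## the Euclidean shortcut property holds downstream
    iu <- match(net$edges$up_node, net$nodes$node_id)
    id <- match(net$edges$down_node, net$nodes$node_id)
    seg <- sqrt((net$nodes$x[iu] - net$nodes$x[id])^2 +
                (net$nodes$y[iu] - net$nodes$y[id])^2)
    expect_equal(seg, net$edges$length_m, tolerance = 1e-9)
  }
})

test_that("target correlation follows the decay-barrier-flow form", {
  pairs <- data.frame(site_a = c("A", "A", "B"), site_b = c("B", "C", "C"),
                      d_w_m = c(0, 5000, 20000),
                      barrier_crossed = c(FALSE, TRUE, FALSE),
                      flow_connected = c(TRUE, TRUE, FALSE))
  cfg <- sim_config(s0 = 0.6, rho_m = 10000, beta = 0.4, gamma = 0.5)
  C <- build_target_correlation(pairs, cfg)
  expect_equal(diag(C), c(A = 1, B = 1, C = 1))
  expect_equal(C["A", "B"], 0.6, tolerance = 1e-6)               # d = 0
  expect_equal(C["A", "C"], 0.6 * exp(-0.5) * 0.4, tolerance = 1e-6)
  expect_equal(C["B", "C"], 0.6 * exp(-2) * 0.5, tolerance = 1e-6)
  expect_true(isSymmetric(C))
  ## beta = gamma = 1: pure distance decay
  cfg2 <- sim_config(s0 = 0.5, rho_m = 10000, beta = 1, gamma = 1)
  C2 <- build_target_correlation(pairs, cfg2)
  expect_equal(C2["A", "C"], 0.5 * exp(-0.5), tolerance = 1e-6)
  ## large distance: correlation vanishes
  pairs$d_w_m <- 1e9
  C3 <- build_target_correlation(pairs, cfg)
  expect_lt(max(abs(C3[upper.tri(C3)])), 1e-8)
})

test_that("PSD repair returns a positive semidefinite unit-diagonal matrix", {
  ## an intentionally indefinite 'correlation' matrix
  C <- matrix(c(1, .9, 0, .9, 1, .9, 0, .9, 1), 3, 3)
  expect_lt(min(eigen(C)$values), 0)
  Cp <- riversync:::nearest_psd(C)
  expect_gte(min(eigen(Cp, symmetric = TRUE)$values), -1e-10)
  expect_equal(diag(Cp), rep(1, 3))
})

test_that("density simulation honours zero-inflation and sampling limits", {
  cfg <- sim_config(n_catchments = 1, n_sites = 5, zero_inflation = 1,
                    sampling_prob = 1, seed = 4)
  C <- diag(5); dimnames(C) <- list(paste0("s", 1:5), paste0("s", 1:5))
  set.seed(9)
  d <- simulate_densities(C, cfg)
  expect_true(all(d$density == 0))
  expect_equal(nrow(d), 5 * cfg$n_years)
  expect_true(all(d$year %in% seq_len(cfg$n_years)))
})

test_that("null panels give mean pairwise Spearman near zero", {
  cfg <- sim_config(n_catchments = 1, n_edges = 10, n_sites = 18,
                    n_barriers = 2, sampling_prob = 1, zero_inflation = 0.05,
                    seed = 21)
  rs <- generate_riverscape(cfg)
  geo <- riverscape_geometry(rs)
  dens <- null_riverscape_densities(rs, cfg, seed = 77)
  rec <- pairwise_synchrony(dens, geo, min_years = 6)
  expect_gt(nrow(rec), 100)
  mc_se <- sd(rec$rho) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$rho)), 3.5 * mc_se + 0.02)
})

test_that("simulated pair synchrony matches the rank image of the target correlation", {
  ## for a bivariate normal with correlation r, the population Spearman is
  ## (6/pi) asin(r/2); estimate both by brute-force simulation and through
  ## the generator, for a flow-connected barrier-free pair at d_W = 0
  r <- 0.6
  set.seed(123)
  ## brute-force oracle: direct bivariate normal draws
  oracle <- replicate(400, {
    z1 <- rnorm(30); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(30)
    cor(z1, z2, method = "spearman")
  })
  ## generator route: 2 sites on one edge at distance ~0, rho huge so the
  ## decay is negligible, no zero-inflation, full sampling
  cfg <- sim_config(n_catchments = 1, n_edges = 1, n_sites = 2,
                    n_barriers = 0, s0 = r, rho_m = 1e12,
                    sampling_prob = 1, zero_inflation = 0, seed = 5)
  rs <- generate_riverscape(cfg)
  geo <- riverscape_geometry(rs)
  geo$d_w_m <- 0   # coincident pair: C_12 = s0 exactly
  C <- build_target_correlation(geo, cfg)
  sim <- replicate(400, {
    d <- simulate_densities(C, cfg)
    w <- merge(d[d$site == d$site[1], ], d[d$site != d$site[1], ], by = "year")
    cor(w$density.x, w$density.y, method = "spearman")
  })
  se <- sqrt(var(oracle) / 400 + var(sim) / 400)
  expect_lt(abs(mean(oracle) - mean(sim)), 4 * se + 0.01)
  ## and both near the closed-form rank image of r
  expect_lt(abs(mean(sim) - (6 / pi) * asin(r / 2)), 0.03)
})
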