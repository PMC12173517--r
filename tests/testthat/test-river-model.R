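test_that("build_network validates tree structure and infers the outlet", {
  net <- build_network(data.frame(edge_id = 1, up_node = "A",
                                  down_node = "B", length_m = 100))
  expect_s3_class(net, "river_network")
  expect_equal(net$outlet, "B")

  y <- y_tree()
  expect_equal(nrow(y$nodes), 4)
  expect_equal(nrow(y$edges), 3)
  expect_equal(y$outlet, "out")

  ## cycle: 3 edges over 3 nodes
  expect_error(build_network(
    data.frame(edge_id = 1:3, up_node = c("A", "B", "C"),
               down_node = c("B", "C", "A"), length_m = 1)),
    "not a tree")
  ## two components
  expect_error(build_network(
    data.frame(edge_id = 1:2, up_node = c("A", "C"),
               down_node = c("B", "D"), length_m = 1)))
  ## nonpositive length
  expect_error(build_network(
    data.frame(edge_id = 1, up_node = "A", down_node = "B",
               length_m = 0)), "length")
  ## braided: a node with two downstream edges
  expect_error(build_network(
    data.frame(edge_id = 1:3, up_node = c("A", "A", "B"),
               down_node = c("B", "C", "D"), length_m = 1)))
})

test_that("edges are re-oriented towards a declared outlet", {
  ## same Y-tree but with one edge stored backwards
  net <- build_network(
    data.frame(edge_id = c("b1", "b2", "stem"),
               up_node = c("h1", "h2", "out"),      # stem reversed
               down_node = c("conf", "conf", "conf"),
               length_m = c(100, 200, 300)),
    outlet = "out")
  expect_equal(net$outlet, "out")
  expect_equal(unname(net$depth_m["conf"]), 300)
  expect_equal(unname(net$depth_m["h1"]), 400)
})

test_that("watercourse distance sums partial offsets across the confluence", {
  net <- y_tree()
  pl <- placements(c("a", "b", "c"), c("b1", "b2", "stem"),
                   c(50, 120, 150), net)
  expect_equal(watercourse_distance(pl, "a", "a", net), 0)
  ## a: 50 m to confluence remain; b: 80 m remain -> 130
  expect_equal(watercourse_distance(pl, "a", "b", net), 130)
  ## a to stem point: 50 + 150
  expect_equal(watercourse_distance(pl, "a", "c", net), 200)
  ## triangle equality when b is on the a--c route
  pl2 <- placements(c("p", "q", "r"), c("b1", "stem", "stem"),
                    c(0, 100, 250), net)
  expect_equal(watercourse_distance(pl2, "p", "r", net),
               watercourse_distance(pl2, "p", "q", net) +
                 watercourse_distance(pl2, "q", "r", net))
})

test_that("flow-connectedness distinguishes downstream routes from branch pairs", {
  net <- y_tree()
  pl <- placements(c("a", "b", "c"), c("b1", "b2", "stem"),
                   c(50, 120, 150), net)
  expect_true(flow_connected(pl, "a", "c", net))   # a drains past c
  expect_true(flow_connected(pl, "c", "a", net))   # symmetric
  expect_false(flow_connected(pl, "a", "b", net))  # different branches
})

test_that("barriers on the open route are counted; coincident ones are not", {
  net <- y_tree()
  pl <- placements(c("a", "b", "c"), c("b1", "b2", "stem"),
                   c(50, 120, 200), net)
  none <- placements(character(), character(), numeric(), net)
  bar <- placements("dam", "stem", 150, net)
  expect_equal(route_barriers(pl, "a", "b", none, net), 0L)
  expect_equal(route_barriers(pl, "a", "c", bar, net), 1L)
  expect_equal(route_barriers(pl, "a", "b", bar, net), 0L)
  ## barrier exactly at a site's own placement does not separate it
  bar_at_c <- placements("dam", "stem", 200, net)
  expect_equal(route_barriers(pl, "a", "c", bar_at_c, net), 0L)
})

test_that("fragment assignment splits the Y-tree at a stem barrier", {
  net <- y_tree()
  sites <- placements(c("s1", "s2", "s3"), c("b1", "b2", "stem"),
                      c(50, 100, 250), net)
  none <- placements(character(), character(), numeric(), net)
  fm0 <- assign_fragments(sites, none, net)
  expect_equal(length(unique(fm0$fragment)), 1L)
  bar <- placements("dam", "stem", 150, net)
  fm <- assign_fragments(sites, bar, net)
  expect_equal(length(unique(fm$fragment)), 2L)
  expect_equal(fm$fragment[1], fm$fragment[2])     # both headwater sites
  expect_false(fm$fragment[1] == fm$fragment[3])
  ## deterministic labels: smallest member id
  expect_setequal(unique(fm$fragment), c("s1", "s3"))
  ## invariant to site enumeration order
  perm <- sites[c(3, 1, 2), ]
  fmp <- assign_fragments(perm, bar, net)
  expect_equal(fmp$fragment[match(fm$site, fmp$site)], fm$fragment)
})

test_that("geometry matches brute-force graph oracles on random riverscapes", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    cc <- random_catchment(seed)
    g <- oracle_graph(cc$network, list(cc$sites, cc$barriers))
    pg <- pair_geometry_table(cc$sites, cc$barriers, cc$network, "c")
    for (k in seq_len(nrow(pg))) {
      a <- pg$site_a[k]; b <- pg$site_b[k]
      expect_equal(pg$d_w_m[k], oracle_distance(g, a, b), tolerance = 1e-9)
      expect_equal(pg$flow_connected[k],
                   oracle_flow_connected(g, a, b, cc$network$outlet))
      expect_equal(pg$n_barriers[k],
                   oracle_route_barriers(g, a, b, cc$barriers$id))
    }
    fm <- assign_fragments(cc$sites, cc$barriers, cc$network)
    expect_true(same_partition(
      split(fm$site, fm$fragment),
      oracle_fragments(g, cc$sites$id, cc$barriers$id)))
  }
})

test_that("pair geometry satisfies metric and consistency invariants", {
  for (seed in 26:30) {
    cc <- random_catchment(seed, n_sites = 10)
    pg <- pair_geometry_table(cc$sites, cc$barriers, cc$network, "c")
    expect_equal(nrow(pg), choose(10, 2))
    expect_true(all(pg$d_e_m <= pg$d_w_m + 1e-6))
    expect_true(all(pg$d_w_m >= 0))
    expect_equal(pg$barrier_crossed, pg$fragment_a != pg$fragment_b)
    expect_equal(pg$barrier_crossed, pg$n_barriers > 0L)
  }
})

test_that("a straight single-edge river has d_E equal to d_W", {
  net <- build_network(
    data.frame(edge_id = 1, up_node = "A", down_node = "B", length_m = 1000),
    nodes = data.frame(node_id = c("A", "B"), x = c(0, 1000), y = c(0, 0)))
  sites <- placements(c("s1", "s2", "s3"), c(1, 1, 1), c(100, 400, 900), net)
  pg <- pair_geometry_table(sites, placements(character(), character(),
                                              numeric(), net), net)
  expect_equal(pg$d_e_m, pg$d_w_m, tolerance = 1e-9)
})

test_that("snapping projects points to the nearest edge deterministically", {
  net <- y_tree()
  ## a point near the stem (stem runs from (0,300) to (0,0))
  sp <- snap_to_network(data.frame(id = "p", x = 30, y = 150), net)
  expect_equal(sp$edge_id, "stem")
  expect_equal(sp$offset_m, 150, tolerance = 1e-9)
  expect_equal(sp$snap_dist_m, 30, tolerance = 1e-9)
})
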