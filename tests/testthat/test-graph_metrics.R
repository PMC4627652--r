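test_that("shortest paths agree with Floyd-Warshall and handle disconnection", {
  expect_equal(shortest_paths(path_net(3))[1, 3], 2)
  # two disconnected dyads
  dyads <- as_net(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                        c(0, 0, 0, 1), c(0, 0, 1, 0)))
  d <- shortest_paths(dyads)
  expect_true(all(is.infinite(d[1:2, 3:4])))
  expect_true(isSymmetric(d))
  set.seed(301)
  for (i in 1:50) {
    a <- random_adjacency(12, runif(1, 0.1, 0.5))
    expect_equal(shortest_paths(as_net(a)), oracle_floyd_warshall(a))
  }
})

test_that("efficiency metrics match closed forms", {
  expect_equal(global_efficiency(complete_net(6)), 1)
  expect_equal(local_efficiency(complete_net(4)), 1)
  expect_equal(global_efficiency(empty_net(5)), 0)
  expect_equal(local_efficiency(empty_net(5)), 0)
  expect_equal(global_efficiency(path_net(3)), 5 / 6)
  st <- star_net(4)
  e <- nodal_efficiency(st)
  expect_equal(e[1], 1)               # centre adjacent to all
  expect_equal(e[2], (1 + 3 / 2) / 4)  # leaf: one direct, three at distance 2
  expect_equal(e[2], 0.625)
  expect_equal(local_efficiency(st), 0)  # neighbour sets edgeless/singleton
})

test_that("mean nodal efficiency equals global efficiency identically", {
  set.seed(302)
  for (i in 1:20) {
    net <- as_net(random_adjacency(15, runif(1, 0.05, 0.6)))
    expect_equal(mean(nodal_efficiency(net)), global_efficiency(net),
                 tolerance = 1e-12)
  }
})

test_that("efficiencies and betweenness match brute-force oracles on random graphs", {
  set.seed(303)
  for (i in 1:50) {
    a <- random_adjacency(10, runif(1, 0.1, 0.6))
    net <- as_net(a)
    expect_equal(local_efficiency(net), oracle_local_eff(a), tolerance = 1e-9)
    expect_equal(nodal_efficiency(net), oracle_nodal_eff(a), tolerance = 1e-9)
    # single-node kernel agrees with the full vector
    j <- sample.int(10, 1)
    expect_equal(connsweep:::nodal_efficiency_single_cpp(a, j - 1L),
                 nodal_efficiency(net)[j], tolerance = 1e-12)
  }
  for (i in 1:50) {
    a <- random_adjacency(11, runif(1, 0.1, 0.5))
    expect_equal(betweenness_centrality(as_net(a)), oracle_betweenness(a),
                 tolerance = 1e-9)
  }
})

test_that("degree and betweenness have their structural values", {
  expect_equal(nodal_degree(complete_net(5)), rep(4, 5))
  expect_equal(nodal_degree(empty_net(4)), rep(0, 4))
  expect_equal(betweenness_centrality(complete_net(6)), rep(0, 6))
  bc <- betweenness_centrality(star_net(4))
  expect_equal(bc[1], choose(4, 2))
  expect_equal(bc[-1], rep(0, 4))
  conn <- random_connectivity(30, seed = 304)
  for (s in c(0.1, 0.25)) {
    net <- binarize_at_sparsity(conn, s)
    expect_equal(sum(nodal_degree(net)), 2 * floor(s * 30 * 29 / 2 + 0.5))
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(305)
  a <- random_adjacency(12, 0.2)
  e0 <- global_efficiency(as_net(a))
  free <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
  pick <- free[sample.int(nrow(free), 5), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    a2 <- a
    a2[pick[r, 1], pick[r, 2]] <- a2[pick[r, 2], pick[r, 1]] <- 1L
    expect_gte(global_efficiency(as_net(a2)), e0)
  }
})

test_that("metrics are equivariant under node relabelling", {
  set.seed(306)
  a <- random_adjacency(10, 0.3)
  perm <- sample(10)
  ap <- a[perm, perm]
  expect_equal(betweenness_centrality(as_net(ap)),
               betweenness_centrality(as_net(a))[perm], tolerance = 1e-12)
  expect_equal(nodal_efficiency(as_net(ap)),
               nodal_efficiency(as_net(a))[perm], tolerance = 1e-12)
  expect_equal(local_efficiency(as_net(ap)), local_efficiency(as_net(a)),
               tolerance = 1e-12)
})

test_that("modularity Q matches the direct double-sum and its bounds", {
  net <- two_cliques_net(4)
  # remove the bridge: two disconnected K4s split perfectly, Q = 0.5
  a <- net$adjacency
  a[1, 5] <- a[5, 1] <- 0L
  expect_equal(modularity_q(as_net(a), rep(1:2, each = 4)), 0.5)
  set.seed(307)
  for (i in 1:20) {
    adj <- random_adjacency(9, runif(1, 0.2, 0.6))
    if (sum(adj) == 0) next
    part <- sample(1:3, 9, replace = TRUE)
    expect_equal(modularity_q(as_net(adj), part), oracle_q(adj, part),
                 tolerance = 1e-12)
    expect_equal(modularity_q(as_net(adj), rep(1, 9)), 0, tolerance = 1e-12)
    expect_gte(modularity_q(as_net(adj), part), -0.5)
    expect_lte(modularity_q(as_net(adj), part), 1)
  }
  expect_error(modularity_q(empty_net(4), c(1, 1, 2, 2)), "edgeless")
})

test_that("spectral partition separates planted cliques deterministically", {
  net <- two_cliques_net(5)
  p <- newman_partition(net)
  expect_equal(p$n_modules, 2L)
  expect_equal(p$assignment[1:5], rep(p$assignment[1], 5))
  expect_equal(p$assignment[6:10], rep(p$assignment[6], 5))
  expect_equal(p$q, oracle_q(net$adjacency, p$assignment), tolerance = 1e-12)
  p2 <- newman_partition(net)
  expect_identical(p$assignment, p2$assignment)
  expect_error(newman_partition(empty_net(3)))
  # spectral splits respect disconnected components
  a <- matrix(0L, 9, 9)
  a[1:3, 1:3] <- 1L; a[4:6, 4:6] <- 1L; a[7:9, 7:9] <- 1L
  diag(a) <- 0L
  expect_gte(newman_partition(as_net(a))$n_modules, 3L)
})

test_that("metric curves export as a tidy table", {
  conn <- random_connectivity(12, seed = 308)
  grid <- sparsity_grid(0.1, 0.3, 0.1)
  cur <- metric_curves(conn, grid)
  expect_length(cur$e_glob, 3L)
  expect_equal(dim(cur$degree), c(12L, 3L))
  tab <- metrics_table(cur, "s1")
  expect_equal(nrow(tab), 3 * 2 + 3 * 3 * 12)
  expect_setequal(unique(tab$metric),
                  c("e_glob", "e_loc", "degree", "efficiency", "betweenness"))
  glob <- tab[tab$metric == "e_glob", ]
  expect_equal(glob$value, cur$e_glob)
})
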