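test_that("fisher_z transforms correlations elementwise and guards the pole", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- -0.3
  z <- fisher_z(r)
  expect_s3_class(z, "connectivity_matrix")
  expect_equal(z$weights[1, 2], 0.5493061443, tolerance = 1e-9)
  expect_equal(z$weights[1, 3], atanh(-0.3))
  expect_equal(diag(z$weights), rep(0, 3), ignore_attr = TRUE)
  expect_equal(z$weights[2, 3], 0)

  r[2, 3] <- r[3, 2] <- 1
  expect_error(fisher_z(r), "Fisher z undefined")
})

test_that("threshold_by_sparsity keeps the strongest positive edges", {
  set.seed(10)
  W <- matrix(0, 5, 5)
  ut <- upper.tri(W)
  W[ut] <- sample(seq(0.1, 1, length.out = 10))
  W <- W + t(W)
  cm <- connectivity_matrix(W)
  net <- threshold_by_sparsity(cm, 0.2)
  # brute-force rank: top-2 of the 10 distinct weights
  top2 <- sort(W[ut], decreasing = TRUE)[1:2]
  kept <- sort(W[net$adjacency & ut], decreasing = TRUE)
  expect_equal(kept, top2)
  expect_equal(net$n_edges, 2L)

  complete <- threshold_by_sparsity(cm, 1)
  expect_equal(complete$n_edges, 10L)
  expect_true(all(complete$adjacency[ut]))

  expect_error(threshold_by_sparsity(cm, 0), "sparsity")
  expect_error(threshold_by_sparsity(cm, -0.1), "sparsity")
})

test_that("rank ties at the cutoff break lexicographically by (row, col)", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[1, 3] <- W[2, 4] <- 0.5   # three tied weights
  W[3, 4] <- 0.9
  W <- W + t(W)
  cm <- connectivity_matrix(W)
  net <- threshold_by_sparsity(cm, 2 / 6)  # keep 2 edges: 0.9 then first tie
  expect_true(net$adjacency[3, 4])
  expect_true(net$adjacency[1, 2])        # (1,2) precedes (1,3) and (2,4)
  expect_equal(net$n_edges, 2L)
})

test_that("thresholding is monotone in sparsity and respects positivity", {
  set.seed(21)
  for (rep in 1:5) {
    W <- matrix(rnorm(100), 10, 10)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    cm <- connectivity_matrix(W)
    prev <- NULL
    for (s in seq(0.1, 1, by = 0.1)) {
      net <- threshold_by_sparsity(cm, s)
      expect_true(all(W[net$adjacency] > 0))
      if (!is.null(prev)) expect_true(all(net$adjacency[prev]))
      prev <- net$adjacency
    }
    # with negatives present the achieved sparsity saturates
    full <- threshold_by_sparsity(cm, 1)
    expect_equal(full$n_edges, sum(W[upper.tri(W)] > 0))
    expect_lt(full$achieved_sparsity, 1)
  }
})

test_that("sparsity_range finds connectivity and all-positive grid points", {
  # 4-node path 1-2-3-4 with strong path weights, weak extra positives
  W <- matrix(0.01, 4, 4)
  diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.8
  W[3, 4] <- W[4, 3] <- 0.7
  cm <- connectivity_matrix(W)
  rng <- sparsity_range(list(cm))
  # 3 spanning edges of 6 pairs: first grid point with round(6 s) >= 3
  expect_equal(rng$s_min, 0.42)
  # all 6 weights positive: densest subject needs all pairs
  expect_equal(rng$s_max, 0.92)

  # an all-negative row isolates a node
  W2 <- W
  W2[4, ] <- W2[, 4] <- -0.2
  diag(W2) <- 0
  expect_error(sparsity_range(list(cm, connectivity_matrix(W2))),
               "subject 2")
})

test_that("efficiencies match closed forms on canonical graphs", {
  k4 <- binary_network(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4),
                                              c(2, 3), c(2, 4), c(3, 4))))
  expect_equal(global_efficiency(k4), 1)
  expect_equal(local_efficiency(k4), 1)

  p3 <- binary_network(adj_from_edges(3, list(c(1, 2), c(2, 3))))
  expect_equal(global_efficiency(p3), 5 / 6)
  expect_equal(local_efficiency(p3), 0)

  empty <- binary_network(matrix(FALSE, 4, 4))
  expect_equal(global_efficiency(empty), 0)

  # star S4: centre reaches all at distance 1, leaves at 1,2,2
  s4 <- binary_network(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4))))
  ne <- nodal_global_efficiency(s4)
  expect_equal(unname(ne[1]), 1)
  expect_equal(unname(ne[2]), 2 / 3)

  iso <- binary_network(adj_from_edges(3, list(c(1, 2))))
  expect_equal(unname(nodal_global_efficiency(iso)[3]), 0)

  expect_error(global_efficiency(binary_network(matrix(FALSE, 1, 1))),
               "fewer than 2")

  # triangle with a pendant node, against the literal-definition oracle
  tp <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
  net <- binary_network(tp)
  expect_equal(local_efficiency(net), oracle_local_eff(tp))
  expect_equal(global_efficiency(net), oracle_global_eff(tp))
})

test_that("efficiencies agree with brute force and igraph on random graphs", {
  set.seed(33)
  for (rep in 1:10) {
    A <- rand_adj(sample(4:12, 1), runif(1, 0.1, 0.6))
    net <- binary_network(A)
    expect_equal(global_efficiency(net), oracle_global_eff(A))
    expect_equal(local_efficiency(net), oracle_local_eff(A))
    expect_equal(unname(nodal_global_efficiency(net)), oracle_nodal_eff(A))
    g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "undirected")
    expect_equal(global_efficiency(net), igraph::global_efficiency(g),
                 tolerance = 1e-12)
  }
})

test_that("degree-matched rewiring preserves the degree sequence exactly", {
  set.seed(44)
  net <- binary_network(rand_adj(30, 0.2))
  for (s in 1:20) {
    rw <- degree_matched_randomize(net, seed = s)
    expect_equal(rowSums(rw$adjacency), rowSums(net$adjacency),
                 ignore_attr = TRUE)
    expect_equal(rw$n_edges, net$n_edges)
    expect_false(any(diag(rw$adjacency)))
  }
  # reproducibility under a fixed seed
  expect_identical(degree_matched_randomize(net, seed = 9)$adjacency,
                   degree_matched_randomize(net, seed = 9)$adjacency)
  # K4 admits no legal swap
  k4 <- binary_network(adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4),
                                              c(2, 3), c(2, 4), c(3, 4))))
  expect_message(rk4 <- degree_matched_randomize(k4, seed = 1), "unchanged")
  expect_identical(rk4$adjacency, k4$adjacency)
})

test_that("rewiring destroys lattice clustering", {
  rl <- lesionhub:::with_seed(2, igraph::sample_smallworld(1, 50, 2, 0))
  A <- igraph::as_adjacency_matrix(rl, sparse = FALSE) > 0
  net <- binary_network(A)
  orig_cc <- igraph::transitivity(rl)
  rewired_cc <- vapply(1:30, function(s) {
    rw <- degree_matched_randomize(net, seed = s)
    igraph::transitivity(igraph::graph_from_adjacency_matrix(
      rw$adjacency * 1, mode = "undirected"))
  }, numeric(1))
  expect_lt(mean(rewired_cc), orig_cc)
})

test_that("sigma exceeds 1 for lattices and is ~1 for its own null class", {
  rl <- lesionhub:::with_seed(3, igraph::sample_smallworld(1, 100, 3, 0))
  net <- binary_network(igraph::as_adjacency_matrix(rl, sparse = FALSE) > 0)
  tm <- small_world_sigma(net, n_random = 50, seed = 1)
  expect_gt(tm$sigma, 1)
  expect_equal(tm$sigma, tm$scaled_locE / tm$scaled_gE)
  expect_equal(tm$n_random, 50)

  # a graph that is itself a rewired null: sigma ~ 1
  null_like <- degree_matched_randomize(net, seed = 5)
  tm0 <- small_world_sigma(null_like, n_random = 100, seed = 2)
  expect_gt(tm0$sigma, 0.85)
  expect_lt(tm0$sigma, 1.15)
})

test_that("metric curves integrate by the trapezoid rule", {
  s <- seq(0.13, 0.47, by = 0.01)
  const <- metric_curve(s, rep(2.5, length(s)))
  expect_equal(auc_over_sparsity(const), 2.5 * (0.47 - 0.13),
               tolerance = 1e-12)

  ramp <- metric_curve(seq(0, 1, by = 0.01), seq(0, 1, by = 0.01))
  expect_equal(auc_over_sparsity(ramp), 0.5)

  tri <- metric_curve(c(0.1, 0.2), c(0, 1))
  expect_equal(auc_over_sparsity(tri), 0.05)

  expect_error(auc_over_sparsity(metric_curve(0.1, 1)), "2 grid points")
  expect_error(metric_curve(c(0.1, 0.3, 0.4), c(1, 2, 3)), "uniform step")
  expect_error(metric_curve(c(0.2, 0.1), c(1, 2)), "ascending")
})

test_that("topology_labels computes per-subject labels at one sparsity or AUC", {
  set.seed(55)
  cms <- replicate(3, {
    W <- matrix(runif(400, -0.2, 0.8), 20, 20)
    connectivity_matrix((W + t(W)) / 2)
  }, simplify = FALSE)
  y <- topology_labels(cms, "net_gE", sparsity = 0.3)
  expect_length(y, 3)
  expect_equal(y[1],
               global_efficiency(threshold_by_sparsity(cms[[1]], 0.3)))
  y_auc <- topology_labels(cms, "net_locE", auc_range = c(0.2, 0.3))
  grid <- seq(0.2, 0.3, by = 0.01)
  expect_equal(y_auc[2], auc_over_sparsity(metric_curve(grid,
    vapply(grid, function(s)
      local_efficiency(threshold_by_sparsity(cms[[2]], s)), numeric(1)))))
})
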