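test_that("average_connectome averages aligned matrices and rejects others", {
  W <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  cm1 <- connectivity_matrix(W)
  expect_equal(average_connectome(list(cm1, cm1))$weights, cm1$weights)

  W2 <- W
  W2[1, 2] <- W2[2, 1] <- 0.6
  cm2 <- connectivity_matrix(W2)
  expect_equal(average_connectome(list(cm1, cm2))$weights[1, 2], 0.4)

  W3 <- W[2:1, 2:1]
  expect_error(average_connectome(list(cm1, connectivity_matrix(W3))),
               "node ids differ.*position 1")
})

test_that("detect_modules separates cliques and recovers planted blocks", {
  # two disconnected 5-cliques: the classic Q = 0.5 case
  A <- matrix(FALSE, 10, 10)
  A[1:5, 1:5] <- TRUE
  A[6:10, 6:10] <- TRUE
  diag(A) <- FALSE
  part <- detect_modules(binary_network(A))
  expect_equal(length(unique(part$module_of)), 2L)
  expect_equal(part$q, 0.5, tolerance = 1e-12)

  # strong planted partition graph
  set.seed(7)
  memb <- rep(1:4, each = 10)
  P <- ifelse(outer(memb, memb, `==`), 0.9, 0.05)
  A2 <- matrix(runif(1600) < P, 40, 40)
  A2[lower.tri(A2)] <- t(A2)[lower.tri(A2)]
  diag(A2) <- FALSE
  part2 <- detect_modules(binary_network(A2), seed = 1)
  expect_equal(mclust::adjustedRandIndex(part2$module_of, memb), 1)
  # refined Q is at least the planted partition's Q
  g <- igraph::graph_from_adjacency_matrix(A2 * 1, mode = "undirected")
  expect_gte(part2$q, igraph::modularity(g, memb) - 1e-12)

  # complete graph: no positive-Q split
  K <- matrix(TRUE, 6, 6); diag(K) <- FALSE
  expect_equal(length(unique(detect_modules(binary_network(K))$module_of)),
               1L)

  expect_error(detect_modules(binary_network(matrix(FALSE, 3, 3))),
               "at least one edge")
})

test_that("module labels are canonical and invariant to node order", {
  set.seed(8)
  memb <- rep(1:3, each = 8)
  P <- ifelse(outer(memb, memb, `==`), 0.85, 0.05)
  A <- matrix(runif(576) < P, 24, 24)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- FALSE
  ids <- paste0("n", 1:24)
  dimnames(A) <- list(ids, ids)
  p1 <- detect_modules(binary_network(A))
  perm <- sample(24)
  p2 <- detect_modules(binary_network(A[perm, perm]))
  expect_equal(p2$module_of[ids], p1$module_of[ids])
  # canonical labels: module 1 is the largest (or first by member index)
  expect_equal(sort(unique(p1$module_of)), 1:3, ignore_attr = TRUE)
})

test_that("consensus_modules flags unstable assignments over the grid", {
  pl <- planted_cm(n_per_block = 20, blocks = 4, seed = 3)
  part <- consensus_modules(pl$cm, seed = 1)
  expect_equal(mclust::adjustedRandIndex(part$module_of, pl$membership), 1)
  expect_length(part$unstable_nodes, 0)
  expect_equal(part$sparsity, 0.15)

  # single-level grid is trivially stable
  p1 <- consensus_modules(pl$cm, s_grid = 0.15, representative_s = 0.15)
  expect_true(all(p1$stability == 1))
  expect_length(p1$unstable_nodes, 0)

  # pure noise: assignments wander across sparsities
  noise <- lesionhub:::with_seed(9, {
    W <- matrix(rnorm(900, 0.2, 0.2), 30, 30)
    connectivity_matrix((W + t(W)) / 2)
  })
  pn <- consensus_modules(noise, seed = 2)
  expect_gt(length(pn$unstable_nodes), 0)
})

test_that("participation coefficient follows its closed forms", {
  # two 4-cliques joined by nothing: all edges within-module
  A <- matrix(FALSE, 8, 8)
  A[1:4, 1:4] <- TRUE
  A[5:8, 5:8] <- TRUE
  diag(A) <- FALSE
  net <- binary_network(A)
  part <- detect_modules(net)
  expect_equal(unname(participation_coefficient(net, part)), rep(0, 8))

  # hub with degree 4 split evenly across 2 modules -> 1 - 2 (1/2)^2 = 0.5
  A2 <- adj_from_edges(7, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                               c(2, 3), c(4, 5), c(6, 7)))
  net2 <- binary_network(A2)
  part2 <- structure(list(node_ids = net2$node_ids,
                          module_of = setNames(c(1, 1, 1, 2, 2, 3, 3),
                                               net2$node_ids),
                          q = NA, sparsity = NA),
                     class = "modular_partition")
  pc <- participation_coefficient(net2, part2)
  # node 1 sits in module 1 with 2 edges in module 1, 2 in module 2
  expect_equal(unname(pc[1]), 0.5)
  # isolated node convention
  A3 <- adj_from_edges(3, list(c(1, 2)))
  net3 <- binary_network(A3)
  part3 <- structure(list(node_ids = net3$node_ids,
                          module_of = setNames(c(1, 1, 2), net3$node_ids),
                          q = NA, sparsity = NA),
                     class = "modular_partition")
  expect_equal(unname(participation_coefficient(net3, part3)[3]), 0)
})

test_that("PC is bounded by 1 - 1/m and attains it for even spread", {
  # node 1 with one edge into each of m modules
  for (m in 2:4) {
    edges <- lapply(seq_len(m), function(j) c(1, 1 + j))
    A <- adj_from_edges(1 + m, edges)
    net <- binary_network(A)
    part <- structure(list(node_ids = net$node_ids,
                           module_of = setNames(c(1, seq_len(m) + 1),
                                                net$node_ids),
                           q = NA, sparsity = NA),
                      class = "modular_partition")
    pc <- participation_coefficient(net, part)
    expect_equal(unname(pc[1]), 1 - 1 / m, tolerance = 1e-12)
    expect_true(all(pc <= 1 - 1 / (m + 1) + 1e-12))
  }
})

test_that("within-module degree is a population z-score per module", {
  A <- adj_from_edges(5, list(c(1, 3), c(2, 3), c(3, 4), c(3, 5),
                              c(4, 5), c(4, 1), c(5, 2)))
  # module {1..5}: kappas: 2,2,4,4,4 -- simpler to check the invariant:
  net <- binary_network(A)
  part <- structure(list(node_ids = net$node_ids,
                         module_of = setNames(rep(1, 5), net$node_ids),
                         q = NA, sparsity = NA),
                    class = "modular_partition")
  wmd <- within_module_degree(net, part)
  expect_equal(mean(wmd), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(wmd^2)), 1, tolerance = 1e-12)

  # hand-computed pattern: within module {1,2,3} the within-degrees are
  # {1,1,2}, so node 3 scores (2 - 4/3) / popsd({1,1,2}) = sqrt(2)
  A2 <- adj_from_edges(7, list(c(1, 3), c(2, 3), c(3, 4), c(3, 5),
                               c(3, 6), c(3, 7),
                               c(1, 4), c(2, 5)))
  net2 <- binary_network(A2)
  part2 <- structure(list(node_ids = net2$node_ids,
                          module_of = setNames(c(1, 1, 1, 2, 2, 2, 2),
                                               net2$node_ids),
                          q = NA, sparsity = NA),
                     class = "modular_partition")
  wmd2 <- within_module_degree(net2, part2)
  # module 1 kappas: node1 = 1 (edge to 3), node2 = 1, node3 = 2
  expect_equal(unname(wmd2[3]), sqrt(2), tolerance = 1e-12)

  # equal within-degrees and singleton modules give 0
  K <- matrix(TRUE, 4, 4); diag(K) <- FALSE
  netK <- binary_network(K)
  partK <- structure(list(node_ids = netK$node_ids,
                          module_of = setNames(c(1, 1, 1, 2), netK$node_ids),
                          q = NA, sparsity = NA),
                     class = "modular_partition")
  wmdK <- within_module_degree(netK, partK)
  expect_equal(unname(wmdK), rep(0, 4))
})

test_that("hub profiles apply the conventional thresholds", {
  pl <- planted_cm(n_per_block = 10, blocks = 3, seed = 5)
  net <- threshold_by_sparsity(pl$cm, 0.2)
  part <- detect_modules(net)
  hp <- hub_profiles(net, part)
  expect_equal(hp$connector, hp$pc > 0.3)
  expect_equal(hp$provincial, hp$wmd > 0)
  expect_equal(hp$high_gE, hp$ge_z > 0)
  expect_true(all(hp$pc >= 0 & hp$pc <= 1))
  expect_equal(mean(hp$ge_z), 0, tolerance = 1e-10)
  # flags replicate the threshold semantics of published nodal tables:
  # pc = 0.56, wmd = -0.34 -> connector only; pc = 0.06, wmd = 1.02 ->
  # provincial; low everything -> no flags
  flags <- function(pc, wmd, gez)
    c(connector = pc > 0.3, provincial = wmd > 0, high_gE = gez > 0)
  expect_equal(flags(0.56, -0.34, 0.69),
               c(connector = TRUE, provincial = FALSE, high_gE = TRUE))
  expect_equal(flags(0.06, 1.02, 0.49),
               c(connector = FALSE, provincial = TRUE, high_gE = TRUE))
  expect_equal(flags(0.09, -0.37, -0.7),
               c(connector = FALSE, provincial = FALSE, high_gE = FALSE))
})
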