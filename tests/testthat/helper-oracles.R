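# Independent brute-force oracles and small fixture builders.
# The oracles deliberately share no code with the package: distances come
# from Floyd-Warshall on the adjacency matrix, efficiencies from the
# definitions applied literally.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_eff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_nodal_eff <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2) return(0)
    oracle_global_eff(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# random symmetric adjacency without self-edges
rand_adj <- function(n, p) {
  A <- matrix(runif(n * n) < p, n, n)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- FALSE
  A
}

# adjacency from an explicit edge list on n nodes
adj_from_edges <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- TRUE
    A[e[2], e[1]] <- TRUE
  }
  A
}

# Watts-Strogatz small-world network (k neighbours each side = k/2)
ws_network <- function(n = 100, k = 6, p = 0.1, seed = 1) {
  g <- lesionhub:::with_seed(seed,
    igraph::sample_smallworld(1, n, k / 2, p))
  binary_network(igraph::as_adjacency_matrix(g, sparse = FALSE) > 0)
}

# block-structured Fisher-z matrix with planted modules
planted_cm <- function(n_per_block = 10, blocks = 4, within = 0.8,
                       between = 0.05, sd = 0.02, seed = 1) {
  n <- n_per_block * blocks
  memb <- rep(seq_len(blocks), each = n_per_block)
  lesionhub:::with_seed(seed, {
    mu <- ifelse(outer(memb, memb, `==`), within, between)
    E <- matrix(rnorm(n * n, sd = sd), n, n)
    W <- mu + (E + t(E)) / 2
    diag(W) <- 0
    list(cm = connectivity_matrix(W), membership = memb)
  })
}

# minimal stand-in for a fitted lesion model, for the pure hub-class logic
fake_model <- function(features, weight, significant) {
  structure(list(label_name = "fake",
                 features = data.frame(
                   feature = features, weight = weight,
                   null_lo = -1, null_hi = 1,
                   significant = significant,
                   sign = ifelse(weight > 0, "+",
                                 ifelse(weight < 0, "-", "0")),
                   stringsAsFactors = FALSE)),
            class = "lesion_model")
}
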