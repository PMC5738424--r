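#' Modular partition of a binary network
#'
#' Community detection by Newman's leading-eigenvector spectral method
#' (igraph's implementation) followed by a Kernighan-Lin-style refinement
#' pass that greedily moves single nodes between modules while modularity Q
#' improves. Module labels are canonicalized by descending module size
#' (ties by smallest member index), so partitions are invariant to node
#' input order.
#'
#' @param net a [binary_network()] with at least one edge.
#' @param seed optional seed (the spectral method is deterministic; the seed
#'   only fixes tie-breaking order in the refinement).
#' @return object of class `modular_partition`: list with `node_ids`,
#'   `module_of` (named integer vector), `q` (modularity), `sparsity`.
#' @export
detect_modules <- function(net, seed = NULL) {
  stopifnot(inherits(net, "binary_network"))
  if (net$n_edges == 0) stop("community detection needs at least one edge")
  g <- as_igraph(net)
  memb <- with_seed(seed, {
    cl <- igraph::cluster_leading_eigen(g)
    refine_partition(net$adjacency, igraph::membership(cl))
  })
  q <- igraph::modularity(g, memb)
  memb <- canonicalize_labels(memb, net$node_ids)
  structure(list(node_ids = net$node_ids,
                 module_of = setNames(memb, net$node_ids),
                 q = q, sparsity = net$sparsity),
            class = "modular_partition")
}

#' @export
print.modular_partition <- function(x, ...) {
  sizes <- sort(table(x$module_of), decreasing = TRUE)
  cat(sprintf("<modular_partition> %d nodes, %d modules (sizes %s), Q = %.4f\n",
              length(x$node_ids), length(sizes),
              paste(sizes, collapse = "/"), x$q))
  invisible(x)
}

# single-node move refinement: repeatedly move a node to the adjacent module
# giving the largest modularity gain, until no positive gain remains.
# With Q = sum_c [L_c/m - (D_c/2m)^2], moving i from module `cur` to `s`
# changes Q by (k_is - k_icur)/m + k_i (D_cur - k_i - D_s) / (2 m^2),
# where D_* are degree sums including i in cur but not in s.
refine_partition <- function(A, memb) {
  memb <- as.integer(memb)
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(deg) / 2
  if (m == 0) return(memb)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      cur <- memb[i]
      mods <- setdiff(sort(unique(memb[A[i, ]])), cur)
      if (length(mods) == 0) next
      k_icur <- sum(A[i, memb == cur])
      D_cur <- sum(deg[memb == cur])
      gain <- vapply(mods, function(s) {
        k_is <- sum(A[i, memb == s])
        D_s <- sum(deg[memb == s])
        (k_is - k_icur) / m + deg[i] * (D_cur - deg[i] - D_s) / (2 * m^2)
      }, numeric(1))
      best <- which.max(gain)
      if (gain[best] > 1e-12) {
        memb[i] <- mods[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

# module 1 = largest module; size ties broken by the smallest member node id
# (names, not positions, so labels are invariant to node input order)
canonicalize_labels <- function(memb, node_ids) {
  memb <- as.integer(factor(memb))
  sizes <- table(memb)
  firsts <- vapply(names(sizes), function(l)
    min(node_ids[memb == as.integer(l)]), character(1))
  ord <- order(-as.integer(sizes), firsts)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  relabel[memb]
}

#' Modular partition with stability over a sparsity grid
#'
#' Runs [detect_modules()] at each sparsity of a grid, returns the partition
#' at the representative sparsity, and flags nodes whose module assignment
#' (after aligning every grid partition to the representative one by maximal
#' overlap) differs from the representative in more than 50% of grid levels.
#'
#' @param cm a [connectivity_matrix()].
#' @param s_grid sparsity grid (default 0.05-0.20, step 0.01).
#' @param representative_s sparsity of the returned partition (default 0.15).
#' @param seed optional seed.
#' @return a `modular_partition` with extra fields `stability` (per-node
#'   fraction of grid levels agreeing with the representative assignment) and
#'   `unstable_nodes` (ids flagged as varying in > 50% of levels).
#' @export
consensus_modules <- function(cm, s_grid = seq(0.05, 0.20, by = 0.01),
                              representative_s = 0.15, seed = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  s_grid <- round(s_grid, 2)
  if (!any(abs(s_grid - representative_s) < 1e-9))
    s_grid <- sort(c(s_grid, representative_s))
  parts <- lapply(seq_along(s_grid), function(g)
    detect_modules(threshold_by_sparsity(cm, s_grid[g]),
                   seed = if (is.null(seed)) NULL else derive_seed(seed, g)))
  rep_idx <- which(abs(s_grid - representative_s) < 1e-9)[1]
  rep_part <- parts[[rep_idx]]
  ref <- rep_part$module_of
  agree <- matrix(NA, length(ref), length(s_grid))
  for (g in seq_along(s_grid)) {
    aligned <- align_to_reference(parts[[g]]$module_of, ref)
    agree[, g] <- aligned == ref
  }
  stability <- rowMeans(agree)
  rep_part$stability <- setNames(stability, names(ref))
  rep_part$unstable_nodes <- names(ref)[stability < 0.5]
  rep_part$s_grid <- s_grid
  rep_part
}

# greedy maximal-overlap label matching of partition `memb` onto `ref`
align_to_reference <- function(memb, ref) {
  tab <- table(memb, ref)
  mapping <- integer(nrow(tab))
  names(mapping) <- rownames(tab)
  used <- integer(0)
  ord <- order(-apply(tab, 1, max))
  next_new <- max(as.integer(colnames(tab))) + 1L
  for (r in ord) {
    prefs <- order(-tab[r, ])
    hit <- prefs[!(as.integer(colnames(tab))[prefs] %in% used) &
                   tab[r, prefs] > 0][1]
    if (is.na(hit)) {
      mapping[r] <- next_new; next_new <- next_new + 1L
    } else {
      lab <- as.integer(colnames(tab))[hit]
      mapping[r] <- lab
      used <- c(used, lab)
    }
  }
  unname(mapping[as.character(memb)])
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_s (k_is / k_i)^2` over modules `s`, where `k_is` is node
#' i's degree into module s and `k_i` its total degree. Nodes with no edges
#' get PC 0 by convention. High PC marks connector hubs.
#'
#' @param net a [binary_network()].
#' @param part a [detect_modules()] partition covering all nodes.
#' @return named numeric vector of PC values in `[0, 1]`.
#' @export
participation_coefficient <- function(net, part) {
  stopifnot(inherits(net, "binary_network"), inherits(part, "modular_partition"))
  check_same_nodes(net, part)
  A <- net$adjacency
  memb <- part$module_of[net$node_ids]
  deg <- rowSums(A)
  mods <- sort(unique(memb))
  kis2 <- matrix(0, nrow(A), length(mods))
  for (s in seq_along(mods)) kis2[, s] <- rowSums(A[, memb == mods[s], drop = FALSE])
  pc <- ifelse(deg > 0, 1 - rowSums((kis2 / pmax(deg, 1))^2), 0)
  setNames(as.numeric(pc), net$node_ids)
}

#' Within-module degree z-score
#'
#' Guimera-Amaral z-score of a node's within-module degree relative to the
#' other members of its module, using the population (n) standard deviation.
#' Modules of size 1 or with zero degree spread give WMD 0 by convention.
#'
#' @inheritParams participation_coefficient
#' @return named numeric vector of WMD values.
#' @export
within_module_degree <- function(net, part) {
  stopifnot(inherits(net, "binary_network"), inherits(part, "modular_partition"))
  check_same_nodes(net, part)
  A <- net$adjacency
  memb <- part$module_of[net$node_ids]
  wmd <- numeric(nrow(A))
  for (s in unique(memb)) {
    in_s <- memb == s
    kappa <- rowSums(A[in_s, in_s, drop = FALSE])
    mu <- mean(kappa)
    sdv <- sqrt(mean((kappa - mu)^2))
    wmd[in_s] <- if (sum(in_s) < 2 || sdv == 0) 0 else (kappa - mu) / sdv
  }
  setNames(wmd, net$node_ids)
}

check_same_nodes <- function(net, part) {
  if (!setequal(net$node_ids, part$node_ids))
    stop("partition does not cover the network's nodes")
  invisible(TRUE)
}

#' Nodal hub profiles of a network
#'
#' Combines participation coefficient, within-module degree and the z-scored
#' nodal global efficiency, and applies the conventional hub thresholds:
#' connector if PC > 0.3, provincial if WMD > 0, high-efficiency if the
#' nodal gE z-score > 0 (z-scored across all nodes of the network).
#'
#' @inheritParams participation_coefficient
#' @param pc_threshold connector threshold on PC (default 0.3).
#' @param wmd_threshold provincial threshold on WMD (default 0).
#' @param gez_threshold threshold on the nodal gE z-score (default 0).
#' @return data.frame with columns node_id, module, pc, wmd, ge_z, connector,
#'   provincial, high_gE.
#' @export
hub_profiles <- function(net, part, pc_threshold = 0.3, wmd_threshold = 0,
                         gez_threshold = 0) {
  pc <- participation_coefficient(net, part)
  wmd <- within_module_degree(net, part)
  ge <- nodal_global_efficiency(net)
  ge_z <- if (sd(ge) > 0) as.numeric(scale(ge)) else numeric(length(ge))
  data.frame(node_id = net$node_ids,
             module = unname(part$module_of[net$node_ids]),
             pc = unname(pc), wmd = unname(wmd), ge_z = ge_z,
             connector = unname(pc > pc_threshold),
             provincial = unname(wmd > wmd_threshold),
             high_gE = ge_z > gez_threshold,
             stringsAsFactors = FALSE)
}
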