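#' Network global efficiency
#'
#' Mean over node pairs of the inverse shortest path length in a binary
#' network (Latora-Marchiori). Unreachable pairs contribute 0.
#'
#' @param net a [binary_network()].
#' @return efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  if (length(net$node_ids) < 2)
    stop("global efficiency undefined for fewer than 2 nodes")
  eff_global_cpp(net$adjacency)
}

#' Network local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbour-induced
#' subgraph (node itself excluded). Neighbourhoods with fewer than 2 nodes
#' score 0.
#'
#' @inheritParams global_efficiency
#' @return efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  eff_local_cpp(net$adjacency)
}

#' Nodal global efficiency
#'
#' For each node, the mean inverse shortest path length to all other nodes
#' (unreachable nodes contribute 0).
#'
#' @inheritParams global_efficiency
#' @return named numeric vector, one value per node.
#' @export
nodal_global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  setNames(as.numeric(eff_nodal_cpp(net$adjacency)), net$node_ids)
}

#' Degree-matched random network
#'
#' Rewires a binary network by attempted double-edge swaps, preserving every
#' node's degree exactly. Swaps that would create self-loops or multi-edges
#' are rejected. By default `10 * n_edges` swaps are attempted. If no legal
#' swap exists (e.g. a complete graph) the input is returned unchanged with a
#' message.
#'
#' @param net a [binary_network()].
#' @param seed optional integer seed; when given, results are reproducible.
#' @param n_attempts number of attempted swaps (default `10 * n_edges`).
#' @return a rewired [binary_network()] with the same degree sequence.
#' @export
degree_matched_randomize <- function(net, seed = NULL, n_attempts = NULL) {
  stopifnot(inherits(net, "binary_network"))
  if (net$n_edges < 2) stop("rewiring needs at least 2 edges")
  if (is.null(n_attempts)) n_attempts <- 10L * net$n_edges
  E <- edge_list0(net)
  n <- length(net$node_ids)
  E2 <- with_seed(seed, rewire_degseq_cpp(E, n, as.integer(n_attempts)))
  if (attr(E2, "accepted") == 0)
    message("no legal degree-preserving swap found; returning network unchanged")
  A <- matrix(FALSE, n, n)
  A[E2 + 1L] <- TRUE
  A <- A | t(A)
  binary_network(A, node_ids = net$node_ids, sparsity = net$sparsity)
}

#' Small-world index sigma
#'
#' Computes network global and local efficiency, scales each by the mean of
#' the same metric over `n_random` degree-matched rewired null networks, and
#' returns sigma = scaled locE / scaled gE. A small-world network typically
#' has sigma > 1.
#'
#' @param net a [binary_network()].
#' @param n_random number of null networks (default 100).
#' @param seed optional integer seed for the null ensemble.
#' @return an object of class `topology_metrics`: list with `sparsity`,
#'   `net_gE`, `net_locE`, `scaled_gE`, `scaled_locE`, `sigma`, `n_random`.
#' @export
small_world_sigma <- function(net, n_random = 100, seed = NULL) {
  stopifnot(inherits(net, "binary_network"), n_random >= 1)
  gE <- global_efficiency(net)
  locE <- local_efficiency(net)
  null_gE <- numeric(n_random)
  null_locE <- numeric(n_random)
  with_seed(seed, {
    for (i in seq_len(n_random)) {
      rnet <- degree_matched_randomize(net)
      null_gE[i] <- eff_global_cpp(rnet$adjacency)
      null_locE[i] <- eff_local_cpp(rnet$adjacency)
    }
  })
  m_gE <- mean(null_gE); m_locE <- mean(null_locE)
  if (m_gE <= 0 || m_locE <= 0)
    stop("degenerate graph: null-network mean efficiency is zero")
  scaled_gE <- gE / m_gE
  scaled_locE <- locE / m_locE
  structure(list(sparsity = net$sparsity, net_gE = gE, net_locE = locE,
                 scaled_gE = scaled_gE, scaled_locE = scaled_locE,
                 sigma = scaled_locE / scaled_gE, n_random = n_random),
            class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf("<topology_metrics> s = %.3f | gE %.4f locE %.4f | scaled %.3f / %.3f | sigma %.3f (%d nulls)\n",
              x$sparsity, x$net_gE, x$net_locE, x$scaled_gE, x$scaled_locE,
              x$sigma, x$n_random))
  invisible(x)
}

#' Metric curve over a sparsity grid
#'
#' Pairs an ascending, uniformly stepped sparsity grid with metric values so
#' the integrated (AUC) value can be computed by [auc_over_sparsity()].
#'
#' @param sparsities ascending numeric grid with uniform step.
#' @param values metric value at each grid point.
#' @return object of class `metric_curve`.
#' @export
metric_curve <- function(sparsities, values) {
  stopifnot(length(sparsities) == length(values))
  if (length(sparsities) >= 2) {
    d <- diff(sparsities)
    if (any(d <= 0)) stop("sparsity grid must be strictly ascending")
    if (max(d) - min(d) > 1e-8) stop("sparsity grid must have a uniform step")
  }
  structure(list(sparsities = as.numeric(sparsities),
                 values = as.numeric(values)), class = "metric_curve")
}

#' Integrate a metric curve over sparsity
#'
#' Trapezoidal integral of the metric values over the sparsity interval
#' `[s1, s2]` spanned by the grid, the usual cumulative (AUC) summary that
#' removes the arbitrariness of a single threshold.
#'
#' @param curve a [metric_curve()] with at least 2 grid points.
#' @return the integrated value.
#' @export
auc_over_sparsity <- function(curve) {
  stopifnot(inherits(curve, "metric_curve"))
  s <- curve$sparsities; v <- curve$values
  if (length(s) < 2) stop("AUC needs at least 2 grid points")
  sum(diff(s) * (v[-1] + v[-length(v)]) / 2)
}

#' Topology metrics for one subject at one sparsity
#'
#' Thresholds a connectivity matrix and returns the topology metrics used as
#' prediction labels (network gE, network locE and, against `n_random`
#' degree-matched nulls, sigma with its scaled components).
#'
#' @param cm a [connectivity_matrix()].
#' @param sparsity threshold in (0, 1].
#' @param n_random null networks for sigma (default 100).
#' @param seed optional seed for the null ensemble.
#' @return a `topology_metrics` object.
#' @export
topology_metrics <- function(cm, sparsity = 0.15, n_random = 100, seed = NULL) {
  small_world_sigma(threshold_by_sparsity(cm, sparsity),
                    n_random = n_random, seed = seed)
}

#' Topology labels for a cohort
#'
#' Computes one topology label per subject, either at a single sparsity or as
#' the AUC over a sparsity grid. These are the `y` labels for
#' [lesion_model()].
#'
#' @param cms list of [connectivity_matrix()] objects.
#' @param label one of `"sigma"`, `"net_gE"`, `"net_locE"`.
#' @param sparsity single sparsity (used when `auc_range` is `NULL`).
#' @param auc_range optional `c(s1, s2)`; labels become AUC over
#'   `seq(s1, s2, step)`.
#' @param step grid step for the AUC (default 0.01).
#' @param n_random null networks per sigma evaluation.
#' @param seed master seed; each subject (and grid level) draws a derived
#'   sub-seed.
#' @return numeric vector, one label per subject.
#' @export
topology_labels <- function(cms, label = c("sigma", "net_gE", "net_locE"),
                            sparsity = 0.15, auc_range = NULL, step = 0.01,
                            n_random = 100, seed = NULL) {
  label <- match.arg(label)
  need_nulls <- label == "sigma"
  one <- function(cm, s, sub_seed) {
    net <- threshold_by_sparsity(cm, s)
    if (need_nulls) small_world_sigma(net, n_random, seed = sub_seed)$sigma
    else if (label == "net_gE") global_efficiency(net)
    else local_efficiency(net)
  }
  vapply(seq_along(cms), function(k) {
    if (is.null(auc_range)) {
      one(cms[[k]], sparsity, if (is.null(seed)) NULL else derive_seed(seed, k))
    } else {
      grid <- round(seq(auc_range[1], auc_range[2], by = step), 2)
      vals <- vapply(seq_along(grid), function(g) {
        one(cms[[k]], grid[g],
            if (is.null(seed)) NULL else derive_seed(seed, k * 1000 + g))
      }, numeric(1))
      auc_over_sparsity(metric_curve(grid, vals))
    }
  }, numeric(1))
}

#' Tidy topology table for a cohort
#'
#' Evaluates `net_gE` and `net_locE` (and optionally `sigma`) for every
#' subject across a sparsity grid and returns a long table
#' (subject, sparsity, metric, value), the package's standard export format.
#'
#' @inheritParams topology_labels
#' @param sparsities sparsity grid.
#' @param metrics metrics to evaluate.
#' @param subject_ids optional subject identifiers.
#' @return data.frame with columns subject, sparsity, metric, value.
#' @export
cohort_topology <- function(cms, sparsities = seq(0.05, 0.45, by = 0.01),
                            metrics = c("net_gE", "net_locE"),
                            n_random = 100, seed = NULL, subject_ids = NULL) {
  metrics <- match.arg(metrics, c("net_gE", "net_locE", "sigma"),
                       several.ok = TRUE)
  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_along(cms))
  sparsities <- round(sparsities, 2)
  rows <- list()
  for (k in seq_along(cms)) {
    for (g in seq_along(sparsities)) {
      net <- threshold_by_sparsity(cms[[k]], sparsities[g])
      vals <- c(net_gE = if ("net_gE" %in% metrics) global_efficiency(net) else NA_real_,
                net_locE = if ("net_locE" %in% metrics) local_efficiency(net) else NA_real_,
                sigma = if ("sigma" %in% metrics)
                  small_world_sigma(net, n_random,
                                    seed = if (is.null(seed)) NULL
                                           else derive_seed(seed, k * 1000 + g))$sigma
                else NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject_ids[k], sparsity = sparsities[g],
        metric = metrics, value = unname(vals[metrics]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
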