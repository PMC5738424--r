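#' Binary network objects
#'
#' A `binary_network` is an undirected, unweighted graph obtained by sparsity
#' thresholding a [connectivity_matrix()] (or supplied directly as a logical
#' adjacency matrix). `sparsity` is the requested fraction of the n(n-1)/2
#' possible edges; `achieved_sparsity` can be lower when fewer positive
#' weights exist than requested.
#'
#' @param adjacency square logical (or 0/1) symmetric matrix, no self-edges.
#' @param node_ids node identifiers (defaults to rownames).
#' @param sparsity requested edge fraction; defaults to the achieved density.
#' @return an object of class `binary_network` with elements `node_ids`,
#'   `adjacency`, `sparsity`, `achieved_sparsity`, `n_edges`.
#' @export
binary_network <- function(adjacency, node_ids = NULL, sparsity = NULL) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency must be square")
  mode(A) <- "logical"
  A[is.na(A)] <- FALSE
  if (!identical(A, t(A))) stop("adjacency must be symmetric")
  if (any(diag(A))) stop("self-edges are not allowed")
  if (is.null(node_ids)) node_ids <- rownames(A)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  dimnames(A) <- list(node_ids, node_ids)
  m <- sum(A[upper.tri(A)])
  dens <- if (n > 1) m / (n * (n - 1) / 2) else 0
  structure(list(node_ids = as.character(node_ids), adjacency = A,
                 sparsity = if (is.null(sparsity)) dens else sparsity,
                 achieved_sparsity = dens, n_edges = m),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %.3f, achieved %.3f)\n",
              length(x$node_ids), x$n_edges, x$sparsity, x$achieved_sparsity))
  invisible(x)
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Ranks the upper-triangle weights and keeps the strongest
#' `round(s * n(n-1)/2)` strictly positive ones as edges (negative and zero
#' weights are never edges). If fewer positive weights exist than requested,
#' all positive weights are kept and the achieved sparsity is recorded. Rank
#' ties at the cutoff are broken by lexicographic (row, column) order so
#' results are identical across platforms.
#'
#' @param cm a [connectivity_matrix()].
#' @param s target sparsity in (0, 1].
#' @return a [binary_network()].
#' @export
threshold_by_sparsity <- function(cm, s) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(s) || length(s) != 1 || s <= 0 || s > 1)
    stop("sparsity must be a single value in (0, 1]")
  W <- cm$weights
  n <- nrow(W)
  ut <- which(upper.tri(W))
  w <- W[ut]
  rowi <- ((ut - 1) %% n) + 1
  coli <- ((ut - 1) %/% n) + 1
  k_req <- round(s * length(ut))
  npos <- sum(w > 0)
  k <- min(k_req, npos)
  A <- matrix(FALSE, n, n)
  if (k > 0) {
    ord <- order(-w, rowi, coli)[seq_len(k)]
    A[ut[ord]] <- TRUE
    A <- A | t(A)
  }
  binary_network(A, node_ids = cm$node_ids, sparsity = s)
}

#' Determine the usable sparsity range for a cohort
#'
#' Scans a sparsity grid (step `step`, values rounded to 2 decimals) and
#' returns `s_min`, the smallest grid sparsity at which every subject's
#' thresholded network is fully connected, and `s_max`, the smallest grid
#' sparsity that retains all positive weights for every subject.
#'
#' @param cms list of [connectivity_matrix()] objects.
#' @param step grid step (default 0.01).
#' @return list with `s_min`, `s_max` and the per-subject minima
#'   `subject_s_min`.
#' @export
sparsity_range <- function(cms, step = 0.01) {
  stopifnot(length(cms) >= 1)
  grid <- round(seq(step, 1, by = step), 2)
  disconnected <- character(0)
  s_min_sub <- numeric(length(cms))
  s_all_sub <- numeric(length(cms))
  for (k in seq_along(cms)) {
    cm <- cms[[k]]
    M <- length(cm$node_ids) * (length(cm$node_ids) - 1) / 2
    npos <- sum(cm$weights[upper.tri(cm$weights)] > 0)
    full <- threshold_by_sparsity(cm, 1)
    if (!connected_cpp(full$adjacency)) {
      disconnected <- c(disconnected, paste0("subject ", k))
      next
    }
    # connectivity is monotone in the edge count: binary search on the grid
    lo <- 1L; hi <- length(grid)
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (connected_cpp(threshold_by_sparsity(cm, grid[mid])$adjacency))
        hi <- mid else lo <- mid + 1L
    }
    s_min_sub[k] <- grid[lo]
    s_all_sub[k] <- grid[which(round(grid * M) >= npos)[1]]
  }
  if (length(disconnected) > 0)
    stop("network disconnected even with all positive edges for: ",
         paste(disconnected, collapse = ", "))
  list(s_min = max(s_min_sub), s_max = max(s_all_sub),
       subject_s_min = s_min_sub)
}

# igraph view of a binary network (used for community detection)
as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency * 1, mode = "undirected")
}

edge_list0 <- function(net) {
  idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  cbind(idx[, 1], idx[, 2]) - 1L
}
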