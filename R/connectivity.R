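#' Connectivity matrix objects
#'
#' A `connectivity_matrix` holds one subject's (or a group-average) symmetric
#' functional connectivity matrix on the Fisher-z scale, with a fixed node
#' ordering and a zero diagonal. Negative z values are retained here; they are
#' discarded only when the network is binarized by [threshold_by_sparsity()].
#'
#' @param weights square numeric matrix of Fisher-z connectivity weights.
#' @param node_ids character vector of node identifiers; defaults to the
#'   rownames of `weights`, or `n1..nN` if unnamed.
#' @param tol symmetry tolerance; asymmetries up to `tol` are averaged out,
#'   larger ones are an error.
#' @return an object of class `connectivity_matrix` with elements `node_ids`
#'   and `weights`.
#' @seealso [fisher_z()], [average_connectome()], [read_connectivity()]
#' @export
connectivity_matrix <- function(weights, node_ids = NULL, tol = 1e-8) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("connectivity matrix must be square")
  if (!all(is.finite(weights))) {
    bad <- which(!is.finite(weights), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite connectivity value at (%d, %d)", bad[1], bad[2]))
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop(sprintf("matrix asymmetric beyond tolerance (max |w - t(w)| = %.3g)", asym))
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(node_ids)) node_ids <- rownames(weights)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length must match matrix dimension")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, weights = weights),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<connectivity_matrix> %d nodes; z range [%.3f, %.3f]; %.1f%% positive edges\n",
              length(x$node_ids), min(ut), max(ut), 100 * mean(ut > 0)))
  invisible(x)
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies `atanh` elementwise to a symmetric Pearson correlation matrix and
#' returns a [connectivity_matrix()] with a zero diagonal. Off-diagonal
#' correlations must lie strictly inside (-1, 1).
#'
#' @param r_matrix square symmetric matrix of Pearson correlations.
#' @param node_ids optional node identifiers (defaults to rownames).
#' @return a `connectivity_matrix` of Fisher-z values.
#' @examples
#' r <- diag(3); r[1, 2] <- r[2, 1] <- 0.5
#' fisher_z(r)$weights[1, 2]  # atanh(0.5) = 0.5493
#' @export
fisher_z <- function(r_matrix, node_ids = NULL) {
  r_matrix <- as.matrix(r_matrix)
  off <- abs(r_matrix) >= 1
  diag(off) <- FALSE
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf("|r| >= 1 off the diagonal at (%d, %d): Fisher z undefined",
                 bad[1], bad[2]))
  }
  z <- atanh(r_matrix)
  diag(z) <- 0
  connectivity_matrix(z, node_ids = node_ids)
}

#' Average a set of connectivity matrices
#'
#' Elementwise mean of Fisher-z matrices sharing an identical node set and
#' ordering; used to build a group-average (e.g. healthy) connectome.
#'
#' @param cms list of [connectivity_matrix()] objects.
#' @return a `connectivity_matrix` of averaged weights.
#' @export
average_connectome <- function(cms) {
  stopifnot(length(cms) >= 1)
  ref <- cms[[1]]
  for (k in seq_along(cms)) {
    ids <- cms[[k]]$node_ids
    if (!identical(ids, ref$node_ids)) {
      first <- which(ids != ref$node_ids)[1]
      if (is.na(first)) first <- min(length(ids), length(ref$node_ids)) + 1
      stop(sprintf("matrix %d: node ids differ from matrix 1 starting at position %d ('%s' vs '%s')",
                   k, first,
                   if (first <= length(ids)) ids[first] else "<missing>",
                   if (first <= length(ref$node_ids)) ref$node_ids[first] else "<missing>"))
    }
  }
  avg <- Reduce(`+`, lapply(cms, `[[`, "weights")) / length(cms)
  connectivity_matrix(avg, node_ids = ref$node_ids)
}
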