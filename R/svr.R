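#' Fit a linear epsilon-SVR
#'
#' Linear support vector regression with the conventional defaults
#' (cost C = 1, epsilon = 0.1), solved by sequential minimal optimization on
#' the dual with a precomputed linear kernel. Features are used as-is (no
#' standardization): lesion-percentage features already share the `[0, 1]`
#' scale, and any covariate columns are min-max scaled to the same range by
#' [assemble_features()].
#'
#' @param X numeric matrix, patients x features (or a
#'   [assemble_features()] `feature_matrix`).
#' @param y numeric label vector, one value per row of `X`.
#' @param cost box constraint C (default 1).
#' @param epsilon width of the insensitive tube (default 0.1).
#' @param tol SMO stopping tolerance (default 1e-3, as in libsvm).
#' @return object of class `svr_model`: list with `weights` (named, one per
#'   feature), `bias`, `dual_coef`, `cost`, `epsilon`.
#' @export
train_svr <- function(X, y, cost = 1, epsilon = 0.1, tol = 1e-3) {
  X <- feature_mat(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 3) stop("need at least 3 training samples")
  if (all(apply(X, 2, function(col) diff(range(col)) == 0)))
    warning("all feature columns are constant: degenerate fit, weights are zero")
  K <- tcrossprod(X)
  fit <- svr_smo_cpp(K, y, cost, epsilon, tol, max_iter = smo_max_iter(nrow(X)))
  if (!fit$converged)
    warning("SMO did not reach the stopping tolerance within the iteration cap")
  w <- drop(crossprod(X, fit$beta))
  structure(list(weights = setNames(as.numeric(w), colnames(X)),
                 bias = fit$b, dual_coef = fit$beta,
                 cost = cost, epsilon = epsilon,
                 iterations = fit$iterations),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> linear eps-SVR: %d features, C = %g, epsilon = %g, bias = %.4f\n",
              length(x$weights), x$cost, x$epsilon, x$bias))
  invisible(x)
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- feature_mat(newdata)
  drop(newdata %*% object$weights) + object$bias
}

smo_max_iter <- function(n) max(200000L, 1000L * n)

# accept plain matrices or feature_matrix objects
feature_mat <- function(X) {
  if (inherits(X, "feature_matrix")) return(X$X)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

# Pearson r with the package convention: 0 (with a warning) when either
# vector has zero variance
safe_pearson <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in predicted or actual labels; accuracy set to 0")
    return(0)
  }
  cor(a, b)
}
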