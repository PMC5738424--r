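#' Fit a lesion model: predict network topology from lesion patterns
#'
#' The central fitting function. A linear epsilon-SVR is trained to predict a
#' network topology label (small-world sigma, network global efficiency or
#' network local efficiency — either at one sparsity or as AUC over a
#' sparsity range) from node-wise lesion-percentage features. Out-of-sample
#' accuracy is the Pearson correlation between leave-one-out predictions and
#' the actual labels; its significance is a one-tailed permutation test in
#' which the labels are shuffled and the whole LOOCV is re-run. Per-feature
#' null weight distributions come from the same permutations (full-sample
#' refits), and a feature is significant when its actual weight falls below
#' the 2.5th or above the 97.5th percentile of its null. Nodes with
#' significant weights are the "lesion hubs".
#'
#' @param x patients x features matrix or [assemble_features()] object.
#' @param y numeric topology label, one per patient (see
#'   [topology_labels()]).
#' @param label_name name of the label (e.g. `"sigma"`, `"net_gE"`,
#'   `"net_locE"`); cosmetic but carried into reports.
#' @param n_perm number of label permutations (default 1000).
#' @param seed master seed for the permutation draws.
#' @param cost,epsilon,tol SVR parameters, see [train_svr()].
#' @param standardize_labels z-score the labels before fitting (default
#'   TRUE). The epsilon-insensitive loss is scale-dependent in y: with the
#'   conventional epsilon = 0.1, a label whose spread is much smaller than
#'   the tube width would be fitted by a constant. Standardizing the target
#'   makes the default parameters meaningful for any topology metric;
#'   weights, bias and predictions are mapped back to the original label
#'   scale, and the permutation nulls use the same transform, so accuracy,
#'   P values and significance flags are unaffected by the choice of units.
#' @param sig_quantiles two-tailed feature-significance percentiles
#'   (default `c(0.025, 0.975)`).
#' @return an object of class `lesion_model` with components `weights`,
#'   `bias`, `predicted`, `actual`, `accuracy_r`, `p_value`, `n_perm`,
#'   `null_accuracies`, and `features` (a data.frame with weight, null
#'   bounds, significance flag and sign per feature). Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @seealso [classify_lesion_hubs()], [split_half_validation()]
#' @examples
#' \donttest{
#' coh <- generate_cohort(synthetic_config(n_patients = 24, n_nodes = 40,
#'                                         seed = 1))
#' y <- topology_labels(coh$matrices, "net_gE", sparsity = 0.15)
#' fm <- assemble_features(coh$patterns)
#' fit <- lesion_model(fm, y, label_name = "net_gE", n_perm = 99, seed = 1)
#' summary(fit)
#' }
#' @export
lesion_model <- function(x, y, label_name = "label", n_perm = 1000, seed = 1,
                         cost = 1, epsilon = 0.1, tol = 1e-3,
                         sig_quantiles = c(0.025, 0.975),
                         standardize_labels = TRUE) {
  X <- feature_mat(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("nrow(x) must equal length(y)")
  if (n < 5) stop("need at least 5 patients for LOOCV")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 40)
    warning("fewer than 40 permutations: feature-weight percentiles are poorly resolved")
  sc <- label_scaling(y, standardize_labels)
  ys <- (y - sc$center) / sc$scale

  full <- train_svr(X, ys, cost = cost, epsilon = epsilon, tol = tol)
  K <- tcrossprod(X)
  mi <- smo_max_iter(n)
  predicted <- as.numeric(svr_loocv_cpp(K, ys, cost, epsilon, tol, mi))
  predicted <- predicted * sc$scale + sc$center
  accuracy_r <- safe_pearson(predicted, y)

  P <- perm_matrix(ys, n_perm, seed)
  null_acc <- as.numeric(svr_perm_loocv_cpp(K, P, cost, epsilon, tol, mi))
  p_value <- (sum(null_acc >= accuracy_r) + 1) / (n_perm + 1)

  B <- svr_perm_fit_cpp(K, P, cost, epsilon, tol, mi)
  W_null <- crossprod(X, B) * sc$scale           # features x n_perm
  bounds <- apply(W_null, 1, quantile, probs = sig_quantiles, names = FALSE)
  feat <- data.frame(feature = colnames(X),
                     weight = unname(full$weights) * sc$scale,
                     null_lo = bounds[1, ], null_hi = bounds[2, ],
                     stringsAsFactors = FALSE)
  feat$significant <- feat$weight < feat$null_lo | feat$weight > feat$null_hi
  feat$sign <- ifelse(feat$weight > 0, "+", ifelse(feat$weight < 0, "-", "0"))
  rownames(feat) <- NULL

  structure(list(label_name = label_name,
                 weights = full$weights * sc$scale,
                 bias = full$bias * sc$scale + sc$center,
                 predicted = predicted, actual = y,
                 accuracy_r = accuracy_r, p_value = p_value, n_perm = n_perm,
                 null_accuracies = null_acc, features = feat,
                 patient_ids = rownames(X), seed = seed,
                 cost = cost, epsilon = epsilon,
                 label_scaling = sc,
                 sig_quantiles = sig_quantiles, call = match.call()),
            class = "lesion_model")
}

label_scaling <- function(y, standardize) {
  s <- sd(y)
  if (!standardize || s == 0) list(center = 0, scale = 1)
  else list(center = mean(y), scale = s)
}

# shared permutation draws: both the model-significance nulls and the
# feature-weight nulls must use the same shuffles, so the permutation matrix
# is a pure function of (y, n_perm, seed)
perm_matrix <- function(y, n_perm, seed) {
  n <- length(y)
  with_seed(derive_seed(seed, 71), {
    vapply(seq_len(n_perm), function(p) y[sample.int(n)], numeric(n))
  })
}

#' @export
print.lesion_model <- function(x, ...) {
  cat(sprintf("Lesion model for '%s' (n = %d patients, %d features)\n",
              x$label_name, length(x$actual), length(x$weights)))
  cat(sprintf("  LOOCV accuracy r = %.3f, permutation P = %.4g (%d permutations)\n",
              x$accuracy_r, x$p_value, x$n_perm))
  cat(sprintf("  significant features: %d\n", sum(x$features$significant)))
  invisible(x)
}

#' @export
summary.lesion_model <- function(object, ...) {
  sig <- object$features[object$features$significant, , drop = FALSE]
  sig <- sig[order(-abs(sig$weight)), , drop = FALSE]
  structure(list(label_name = object$label_name,
                 n = length(object$actual),
                 n_features = length(object$weights),
                 accuracy_r = object$accuracy_r, p_value = object$p_value,
                 n_perm = object$n_perm, significant = sig),
            class = "summary.lesion_model")
}

#' @export
print.summary.lesion_model <- function(x, ...) {
  cat(sprintf("Lesion model for '%s'\n", x$label_name))
  cat(sprintf("  patients: %d   features: %d\n", x$n, x$n_features))
  cat(sprintf("  LOOCV accuracy r = %.3f, one-tailed permutation P = %.4g\n",
              x$accuracy_r, x$p_value))
  if (nrow(x$significant) == 0) {
    cat("  no significant feature weights\n")
  } else {
    cat(sprintf("  %d significant feature weight(s):\n", nrow(x$significant)))
    print(x$significant, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.lesion_model <- function(object, ...) object$weights

#' @export
fitted.lesion_model <- function(object, ...)
  setNames(object$predicted, object$patient_ids)

#' @export
residuals.lesion_model <- function(object, ...)
  setNames(object$actual - object$predicted, object$patient_ids)

#' @export
predict.lesion_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  newdata <- feature_mat(newdata)
  newdata <- newdata[, names(object$weights), drop = FALSE]
  drop(newdata %*% object$weights) + object$bias
}

#' @export
plot.lesion_model <- function(x, ...) {
  graphics::plot(x$actual, x$predicted,
                 xlab = paste("actual", x$label_name),
                 ylab = paste("LOOCV-predicted", x$label_name),
                 main = sprintf("%s: r = %.3f, P = %.3g", x$label_name,
                                x$accuracy_r, x$p_value), ...)
  graphics::abline(stats::lm(x$predicted ~ x$actual), lty = 2)
  invisible(x)
}

#' Leave-one-out cross-validated prediction accuracy
#'
#' Runs one SVR fit per held-out patient, assembles the predictions in
#' patient order and returns the Pearson correlation between predicted and
#' actual labels. LOOCV accuracy is invariant to patient ordering.
#'
#' @inheritParams train_svr
#' @param standardize_labels z-score labels before fitting, mapping
#'   predictions back afterwards (default TRUE; see [lesion_model()]).
#' @return list with `predicted` and `accuracy_r`.
#' @export
loocv_accuracy <- function(X, y, cost = 1, epsilon = 0.1, tol = 1e-3,
                           standardize_labels = TRUE) {
  X <- feature_mat(X)
  y <- as.numeric(y)
  if (nrow(X) < 5) stop("LOOCV needs at least 5 patients")
  sc <- label_scaling(y, standardize_labels)
  K <- tcrossprod(X)
  pred <- as.numeric(svr_loocv_cpp(K, (y - sc$center) / sc$scale, cost,
                                   epsilon, tol, smo_max_iter(nrow(X))))
  pred <- pred * sc$scale + sc$center
  list(predicted = setNames(pred, rownames(X)),
       accuracy_r = safe_pearson(pred, y))
}

#' Permutation significance of the LOOCV accuracy
#'
#' Shuffles the labels `n_perm` times, re-runs the full LOOCV for each
#' shuffle, and returns the one-tailed permutation P value
#' `P = (#\{null accuracy >= actual\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams lesion_model
#' @param X feature matrix.
#' @return list with `p_value`, `accuracy_r`, `null_accuracies`.
#' @export
permutation_model_significance <- function(X, y, n_perm = 1000, seed = 1,
                                           cost = 1, epsilon = 0.1,
                                           tol = 1e-3,
                                           standardize_labels = TRUE) {
  X <- feature_mat(X)
  y <- as.numeric(y)
  if (n_perm < 1) stop("n_perm must be >= 1")
  sc <- label_scaling(y, standardize_labels)
  ys <- (y - sc$center) / sc$scale
  K <- tcrossprod(X)
  mi <- smo_max_iter(nrow(X))
  pred <- as.numeric(svr_loocv_cpp(K, ys, cost, epsilon, tol, mi))
  acc <- safe_pearson(pred, ys)
  P <- perm_matrix(ys, n_perm, seed)
  null_acc <- as.numeric(svr_perm_loocv_cpp(K, P, cost, epsilon, tol, mi))
  list(p_value = (sum(null_acc >= acc) + 1) / (n_perm + 1),
       accuracy_r = acc, null_accuracies = null_acc)
}

#' Permutation significance of the feature weights
#'
#' Null per-feature weight distributions are obtained from full-sample refits
#' under the same label shuffles used for the model-significance test (same
#' seed, same draws); a feature is significant when its actual weight falls
#' below the lower or above the upper percentile of its own null.
#'
#' @inheritParams permutation_model_significance
#' @param sig_quantiles percentile pair (default `c(0.025, 0.975)`).
#' @return data.frame with feature, weight, null bounds, significance, sign.
#' @export
feature_weight_significance <- function(X, y, n_perm = 1000, seed = 1,
                                        cost = 1, epsilon = 0.1, tol = 1e-3,
                                        sig_quantiles = c(0.025, 0.975),
                                        standardize_labels = TRUE) {
  X <- feature_mat(X)
  y <- as.numeric(y)
  if (n_perm < 40)
    warning("fewer than 40 permutations: feature-weight percentiles are poorly resolved")
  sc <- label_scaling(y, standardize_labels)
  ys <- (y - sc$center) / sc$scale
  full <- train_svr(X, ys, cost = cost, epsilon = epsilon, tol = tol)
  K <- tcrossprod(X)
  P <- perm_matrix(ys, n_perm, seed)
  B <- svr_perm_fit_cpp(K, P, cost, epsilon, tol, smo_max_iter(nrow(X)))
  W_null <- crossprod(X, B) * sc$scale
  bounds <- apply(W_null, 1, quantile, probs = sig_quantiles, names = FALSE)
  out <- data.frame(feature = colnames(X),
                    weight = unname(full$weights) * sc$scale,
                    null_lo = bounds[1, ], null_hi = bounds[2, ],
                    stringsAsFactors = FALSE)
  out$significant <- out$weight < out$null_lo | out$weight > out$null_hi
  out$sign <- ifelse(out$weight > 0, "+", ifelse(out$weight < 0, "-", "0"))
  rownames(out) <- NULL
  out
}

#' Classify lesion hubs into integration vs segregation effects
#'
#' Combines the per-feature significance of the three lesion models. A node
#' is an integration-effect hub when its lesion shifts the network towards
#' more global processing: significant negative weight for network locE or
#' sigma, and/or significant positive weight for network gE. The segregation
#' class is the mirror image. Nodes whose significant signs conflict between
#' the two patterns are flagged `"unclassified"`; nodes significant in no
#' model are omitted.
#'
#' @param locE,gE,sigma [lesion_model()] fits for network locE, network gE
#'   and sigma, on the same feature set.
#' @return data.frame of class `lesion_hub_table` with one row per hub:
#'   node_id, per-model sign (`"+"`/`"-"`, `NA` when not significant) and
#'   `effect_class` in `c("integration", "segregation", "unclassified")`.
#' @export
classify_lesion_hubs <- function(locE, gE, sigma) {
  fits <- list(net_locE = locE, net_gE = gE, sigma = sigma)
  stopifnot(all(vapply(fits, inherits, logical(1), "lesion_model")))
  feats <- lapply(fits, function(f) f$features$feature)
  if (!all(vapply(feats, identical, logical(1), feats[[1]])))
    stop("the three models were fitted on different feature sets")
  sig_sign <- vapply(fits, function(f)
    ifelse(f$features$significant, f$features$sign, NA_character_),
    character(length(feats[[1]])))
  if (is.null(dim(sig_sign))) sig_sign <- matrix(sig_sign, nrow = 1,
                                                 dimnames = list(NULL, names(fits)))
  any_sig <- rowSums(!is.na(sig_sign)) > 0
  integ <- (!is.na(sig_sign[, "net_locE"]) & sig_sign[, "net_locE"] == "-") |
    (!is.na(sig_sign[, "sigma"]) & sig_sign[, "sigma"] == "-") |
    (!is.na(sig_sign[, "net_gE"]) & sig_sign[, "net_gE"] == "+")
  segr <- (!is.na(sig_sign[, "net_locE"]) & sig_sign[, "net_locE"] == "+") |
    (!is.na(sig_sign[, "sigma"]) & sig_sign[, "sigma"] == "+") |
    (!is.na(sig_sign[, "net_gE"]) & sig_sign[, "net_gE"] == "-")
  class_of <- ifelse(integ & segr, "unclassified",
                     ifelse(integ, "integration",
                            ifelse(segr, "segregation", NA_character_)))
  out <- data.frame(node_id = feats[[1]],
                    net_locE = sig_sign[, "net_locE"],
                    net_gE = sig_sign[, "net_gE"],
                    sigma = sig_sign[, "sigma"],
                    effect_class = class_of,
                    stringsAsFactors = FALSE)[any_sig, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lesion_hub_table", "data.frame")
  out
}

#' Split-half validation of a lesion model
#'
#' Randomly divides the patients into two subgroups (sizes differing by at
#' most 1) and runs the full LOOCV + permutation pipeline in each half.
#'
#' @inheritParams lesion_model
#' @return list of two `lesion_model` objects (`half1`, `half2`) plus the
#'   index split.
#' @export
split_half_validation <- function(x, y, label_name = "label", n_perm = 1000,
                                  seed = 1, ...) {
  X <- feature_mat(x)
  n <- nrow(X)
  if (n < 10) stop("split-half validation needs at least 10 patients")
  idx <- with_seed(derive_seed(seed, 37), sample.int(n))
  half1 <- sort(idx[seq_len(n %/% 2)])
  half2 <- sort(idx[(n %/% 2 + 1):n])
  list(half1 = lesion_model(X[half1, , drop = FALSE], y[half1],
                            label_name = paste0(label_name, ".half1"),
                            n_perm = n_perm, seed = derive_seed(seed, 38), ...),
       half2 = lesion_model(X[half2, , drop = FALSE], y[half2],
                            label_name = paste0(label_name, ".half2"),
                            n_perm = n_perm, seed = derive_seed(seed, 39), ...),
       split = list(half1 = half1, half2 = half2))
}

#' Group comparison of a topology metric across sparsities
#'
#' Two-sample t-test of a network metric between patients and controls at
#' each sparsity of a common grid, with Benjamini-Hochberg FDR correction
#' across the grid levels.
#'
#' @param patient_metrics,control_metrics numeric matrices
#'   (subjects x sparsities) or lists of [metric_curve()] objects on a common
#'   grid.
#' @param sparsities the grid (taken from the curves when lists are given).
#' @param alpha FDR level (default 0.05).
#' @return data.frame with sparsity, group means, t statistic, raw and
#'   BH-adjusted p, significance flag and direction
#'   (`"decrease"`/`"increase"` of patients relative to controls).
#' @export
group_topology_comparison <- function(patient_metrics, control_metrics,
                                      sparsities = NULL, alpha = 0.05) {
  as_mat <- function(x) {
    if (is.list(x) && all(vapply(x, inherits, logical(1), "metric_curve"))) {
      s <- x[[1]]$sparsities
      for (c2 in x) if (!isTRUE(all.equal(c2$sparsities, s)))
        stop("metric curves are not on a common sparsity grid")
      m <- do.call(rbind, lapply(x, `[[`, "values"))
      attr(m, "sparsities") <- s
      m
    } else as.matrix(x)
  }
  P <- as_mat(patient_metrics); C <- as_mat(control_metrics)
  if (ncol(P) != ncol(C)) stop("groups are not on a common sparsity grid")
  if (nrow(P) < 2 || nrow(C) < 2) stop("each group needs at least 2 subjects")
  if (is.null(sparsities))
    sparsities <- attr(P, "sparsities") %||% seq_len(ncol(P))
  res <- lapply(seq_len(ncol(P)), function(g) {
    tt <- t.test(P[, g], C[, g])
    data.frame(sparsity = sparsities[g],
               mean_patient = mean(P[, g]), mean_control = mean(C[, g]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out$direction <- ifelse(out$mean_patient < out$mean_control,
                          "decrease", "increase")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
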