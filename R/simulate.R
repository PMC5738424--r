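#' Configuration for the synthetic lesion cohort generator
#'
#' Bundles every tunable of the generator. Defaults emulate the cohort
#' structure the pipeline is designed for: 96 patients, 180 cortical nodes in
#' 4 modules, sparse spatially contiguous lesions with strongly non-uniform
#' node-wise lesion frequency, and a planted coupling in which damage to a
#' small set of "effector" hub nodes attenuates their connectivity and hence
#' shifts the network's topology.
#'
#' @param n_nodes number of nodes (default 180).
#' @param n_modules number of modules (default 4).
#' @param n_patients cohort size (default 96).
#' @param within_mean,between_mean mean Fisher-z connectivity within and
#'   between modules (defaults 0.5 / 0.12).
#' @param weight_sd standard deviation of the connectivity weights (0.12).
#' @param connector_strength mean z of an effector's cross-module
#'   connections under `"connector"` placement (default 0.58, slightly above
#'   the within-module mean, which makes effectors genuine high-degree
#'   connector hubs whose loss visibly reshapes the topology).
#' @param n_effectors number of planted effector nodes (default 6).
#' @param effector_placement `"connector"` (boosted cross-module weights) or
#'   `"provincial"` (boosted within-module weights).
#' @param coord_sd spatial scatter of nodes around their module centre (1).
#' @param knn_k neighbours in the spatial k-nearest-neighbour adjacency used
#'   to grow contiguous lesion blobs (default 6).
#' @param blob_size_mean,blob_size_sd blob size distribution in nodes
#'   (rounded normal, clipped to `[3, 30]`; defaults 10 / 4).
#' @param p_second_blob probability a patient has a second blob (0.35).
#' @param lp_shape1,lp_shape2 Beta parameters of the lesion fraction inside a
#'   blob (defaults 2 / 2).
#' @param blob_decay core-to-periphery severity decay: the lesion fraction of
#'   the k-th node added to a blob is scaled by
#'   `1 - blob_decay * (k - 1) / (size - 1)`, so damage is deepest at the
#'   vascular core and shallower at the rim (default 0.5).
#' @param seed_weight_sd log-normal sd of the per-node blob-seed propensity
#'   ("vascular" heterogeneity; default 1).
#' @param effector_seed_boost multiplier on the seed propensity of effectors
#'   and their spatial neighbours, mimicking the vascular over-exposure of
#'   hub territories (default 12).
#' @param attenuation exponent alpha of the multiplicative edge attenuation
#'   `(1 - lp_i)^alpha (1 - lp_j)^alpha` (default 1).
#' @param noise_sd sd of the additive Gaussian observation noise on the
#'   patient connectivity weights (default 0.03).
#' @param node_voxels nominal voxel count per node, used only to report a
#'   total lesion volume (default 250).
#' @param null_mode when `TRUE`, lesion patterns are shuffled across patients
#'   after the matrices are generated, destroying the lesion-topology
#'   coupling while preserving both marginals.
#' @param seed master seed; every stage derives its own sub-seed.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 180, n_modules = 4, n_patients = 96,
                             within_mean = 0.5, between_mean = 0.12,
                             weight_sd = 0.12, connector_strength = 0.58,
                             n_effectors = 6,
                             effector_placement = c("connector", "provincial"),
                             coord_sd = 1, knn_k = 6,
                             blob_size_mean = 10, blob_size_sd = 4,
                             p_second_blob = 0.35,
                             lp_shape1 = 2, lp_shape2 = 2, blob_decay = 0.5,
                             seed_weight_sd = 1, effector_seed_boost = 12,
                             attenuation = 1, noise_sd = 0.03,
                             node_voxels = 250, null_mode = FALSE, seed = 1) {
  effector_placement <- match.arg(effector_placement)
  cfg <- list(n_nodes = n_nodes, n_modules = n_modules,
              n_patients = n_patients, within_mean = within_mean,
              between_mean = between_mean, weight_sd = weight_sd,
              connector_strength = connector_strength,
              n_effectors = n_effectors,
              effector_placement = effector_placement,
              coord_sd = coord_sd, knn_k = knn_k,
              blob_size_mean = blob_size_mean, blob_size_sd = blob_size_sd,
              p_second_blob = p_second_blob,
              lp_shape1 = lp_shape1, lp_shape2 = lp_shape2,
              blob_decay = blob_decay,
              seed_weight_sd = seed_weight_sd,
              effector_seed_boost = effector_seed_boost,
              attenuation = attenuation, noise_sd = noise_sd,
              node_voxels = node_voxels, null_mode = isTRUE(null_mode),
              seed = as.integer(seed))
  counts <- c("n_nodes", "n_modules", "n_patients", "n_effectors", "knn_k")
  for (f in counts) if (cfg[[f]] < 1) stop(f, " must be positive")
  if (cfg$within_mean <= cfg$between_mean)
    stop("within-module mean connectivity must exceed the between-module mean")
  if (cfg$n_effectors > cfg$n_nodes) stop("more effectors than nodes")
  structure(cfg, class = "synthetic_config")
}

# module assignment, 3-D coordinates, spatial kNN adjacency, effector ids and
# blob-seed propensities -- all deterministic given cfg$seed
cohort_geometry <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 1), {
    n <- cfg$n_nodes
    modules <- rep(seq_len(cfg$n_modules), length.out = n)
    modules <- sort(modules)
    centers <- matrix(rnorm(cfg$n_modules * 3, sd = 4), cfg$n_modules, 3)
    coords <- centers[modules, , drop = FALSE] +
      matrix(rnorm(n * 3, sd = cfg$coord_sd), n, 3)
    D <- as.matrix(dist(coords))
    diag(D) <- Inf
    k <- min(cfg$knn_k, n - 1)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) adj[i, order(D[i, ])[seq_len(k)]] <- TRUE
    adj <- adj | t(adj)
    effectors <- integer(0)
    if (cfg$n_effectors > 0) {
      # spread effectors across modules round-robin
      per_mod <- split(seq_len(n), modules)
      slots <- rep(seq_len(cfg$n_modules), length.out = cfg$n_effectors)
      effectors <- unlist(lapply(seq_len(cfg$n_modules), function(m) {
        need <- sum(slots == m)
        if (need == 0) return(integer(0))
        sample(per_mod[[m]], need)
      }))
    }
    seed_w <- exp(rnorm(n, sd = cfg$seed_weight_sd))
    if (length(effectors) > 0) {
      near_eff <- unique(c(effectors, which(rowSums(
        adj[, effectors, drop = FALSE]) > 0)))
      seed_w[near_eff] <- seed_w[near_eff] * cfg$effector_seed_boost
    }
    list(modules = modules, coords = coords, knn = adj,
         effectors = sort(effectors), seed_weights = seed_w / sum(seed_w),
         node_ids = paste0("n", seq_len(n)))
  })
}

#' Generate the healthy base connectome
#'
#' Block-structured Fisher-z matrix: within-module weights are drawn with a
#' higher mean than between-module weights, and planted effector nodes
#' receive boosted cross-module (connector placement) or within-module
#' (provincial placement) weights, making them genuine hubs of the
#' thresholded network.
#'
#' @param cfg a [synthetic_config()].
#' @return a [connectivity_matrix()]; the module assignment, effector ids and
#'   node coordinates are attached as attribute `"geometry"`.
#' @export
generate_healthy_base <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  geom <- cohort_geometry(cfg)
  n <- cfg$n_nodes
  W <- with_seed(derive_seed(cfg$seed, 2), {
    same <- outer(geom$modules, geom$modules, `==`)
    mu <- ifelse(same, cfg$within_mean, cfg$between_mean)
    if (length(geom$effectors) > 0) {
      for (e in geom$effectors) {
        if (cfg$effector_placement == "connector")
          mu[e, !same[e, ]] <- mu[!same[e, ], e] <- cfg$connector_strength
        else
          mu[e, same[e, ]] <- mu[same[e, ], e] <-
            cfg$within_mean + 0.3 * (cfg$within_mean - cfg$between_mean)
      }
    }
    z <- matrix(rnorm(n * n, sd = cfg$weight_sd), n, n)
    z <- (z + t(z)) / sqrt(2)
    mu + z
  })
  cm <- connectivity_matrix(W, node_ids = geom$node_ids)
  attr(cm, "geometry") <- geom
  cm
}

#' Generate spatially contiguous lesion patterns
#'
#' Each patient receives one or two contiguous blobs grown over the spatial
#' k-nearest-neighbour adjacency from seed nodes drawn with non-uniform
#' ("vascular") propensities; lesion fractions inside a blob follow a Beta
#' distribution and are zero elsewhere.
#'
#' @param cfg a [synthetic_config()].
#' @return list of [lesion_pattern()] objects of length `n_patients`.
#' @export
generate_lesion_patterns <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  geom <- cohort_geometry(cfg)
  n <- cfg$n_nodes
  nbrs <- apply(geom$knn, 1, which, simplify = FALSE)
  with_seed(derive_seed(cfg$seed, 3), {
    lapply(seq_len(cfg$n_patients), function(p) {
      lp <- numeric(n)
      n_blobs <- 1 + rbinom(1, 1, cfg$p_second_blob)
      for (b in seq_len(n_blobs)) {
        target <- round(rnorm(1, cfg$blob_size_mean, cfg$blob_size_sd))
        target <- max(3, min(30, target, n))
        blob <- sample.int(n, 1, prob = geom$seed_weights)
        while (length(blob) < target) {
          frontier <- setdiff(unique(unlist(nbrs[blob])), blob)
          if (length(frontier) == 0) break
          blob <- c(blob, frontier[sample.int(length(frontier), 1)])
        }
        sev <- rbeta(length(blob), cfg$lp_shape1, cfg$lp_shape2)
        if (length(blob) > 1)
          sev <- sev * (1 - cfg$blob_decay * (seq_along(blob) - 1) /
                          (length(blob) - 1))
        lp[blob] <- pmax(lp[blob], sev)
      }
      lesion_pattern(setNames(lp, geom$node_ids),
                     patient_id = sprintf("p%03d", p),
                     total_volume = sum(lp) * cfg$node_voxels)
    })
  })
}

#' Apply the lesion forward model to the base connectome
#'
#' Multiplicative attenuation: each edge weight becomes
#' `base_ij * (1 - lp_i)^alpha * (1 - lp_j)^alpha` plus symmetric Gaussian
#' observation noise. A fully lesioned node (lp = 1, alpha = 1, no noise)
#' therefore loses all of its connectivity.
#'
#' @param base the healthy [connectivity_matrix()].
#' @param lp a [lesion_pattern()] or numeric lesion-fraction vector.
#' @param cfg a [synthetic_config()] (supplies `attenuation` and `noise_sd`).
#' @param noise_seed optional seed for the observation noise; `NA` disables
#'   noise entirely.
#' @return a [connectivity_matrix()] for this patient.
#' @export
apply_lesion_forward_model <- function(base, lp, cfg, noise_seed = NULL) {
  stopifnot(inherits(base, "connectivity_matrix"))
  if (inherits(lp, "lesion_pattern")) lp <- lp$lp
  if (length(lp) != length(base$node_ids))
    stop("lesion vector length does not match the connectome")
  f <- (1 - lp)^cfg$attenuation
  W <- base$weights * outer(f, f)
  if (!is.na(noise_seed %||% 0) && cfg$noise_sd > 0) {
    E <- with_seed(noise_seed,
                   matrix(rnorm(length(W), sd = cfg$noise_sd), nrow(W)))
    W <- W + (E + t(E)) / sqrt(2)
  }
  diag(W) <- 0
  connectivity_matrix(W, node_ids = base$node_ids)
}

#' Generate a full synthetic cohort
#'
#' Composes the base-connectome, lesion-pattern and forward-model generators.
#' In `null_mode` the lesion patterns are shuffled across patients *after*
#' the matrices are generated, which destroys the lesion-topology coupling
#' while leaving both marginal distributions untouched. Ground-truth effect
#' signs per (effector, label) are derived from a single-node-deletion
#' oracle: the label is recomputed on the noise-free base with that node
#' fully lesioned, and the sign of the change is recorded.
#'
#' @param cfg a [synthetic_config()].
#' @param ground_truth compute the deletion-oracle sign table (default TRUE;
#'   involves sigma null ensembles, so can be disabled for speed).
#' @param oracle_sparsity sparsity at which the oracle evaluates topology
#'   (default 0.15).
#' @param oracle_n_random null networks per oracle sigma evaluation (100).
#' @return object of class `synthetic_cohort`: list with `base` (healthy
#'   connectome), `matrices` (per-patient [connectivity_matrix()]),
#'   `patterns` (per-patient [lesion_pattern()]), `effectors` (node ids),
#'   `ground_truth` (data.frame node, label, delta, sign), `geometry`, `cfg`.
#' @export
generate_cohort <- function(cfg, ground_truth = TRUE, oracle_sparsity = 0.15,
                            oracle_n_random = 100) {
  stopifnot(inherits(cfg, "synthetic_config"))
  base <- generate_healthy_base(cfg)
  geom <- attr(base, "geometry")
  patterns <- generate_lesion_patterns(cfg)
  matrices <- lapply(seq_along(patterns), function(i)
    apply_lesion_forward_model(base, patterns[[i]], cfg,
                               noise_seed = derive_seed(cfg$seed, 100 + i)))
  if (cfg$null_mode) {
    shuf <- with_seed(derive_seed(cfg$seed, 4),
                      sample.int(cfg$n_patients))
    patterns <- patterns[shuf]
    for (i in seq_along(patterns)) patterns[[i]]$patient_id <-
      sprintf("p%03d", i)
  }
  gt <- NULL
  if (ground_truth && length(geom$effectors) > 0)
    gt <- deletion_oracle(base, geom$effectors, cfg, oracle_sparsity,
                          oracle_n_random)
  structure(list(base = base, matrices = matrices, patterns = patterns,
                 effectors = geom$node_ids[geom$effectors],
                 ground_truth = gt, geometry = geom, cfg = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d nodes, %d effectors%s\n",
              length(x$matrices), length(x$base$node_ids),
              length(x$effectors),
              if (x$cfg$null_mode) " [null mode]" else ""))
  invisible(x)
}

# single-node-deletion oracle: expected sign of each label change when an
# effector is fully lesioned on the noise-free base
deletion_oracle <- function(base, effectors, cfg, sparsity, n_random) {
  labels <- c("net_gE", "net_locE", "sigma")
  eval_labels <- function(cm, sd_seed) {
    net <- threshold_by_sparsity(cm, sparsity)
    tm <- small_world_sigma(net, n_random, seed = sd_seed)
    c(net_gE = tm$net_gE, net_locE = tm$net_locE, sigma = tm$sigma)
  }
  base_vals <- eval_labels(base, derive_seed(cfg$seed, 5))
  rows <- lapply(seq_along(effectors), function(k) {
    e <- effectors[k]
    lp <- numeric(length(base$node_ids))
    lp[e] <- 1
    lesioned <- apply_lesion_forward_model(base, lp, cfg, noise_seed = NA)
    vals <- eval_labels(lesioned, derive_seed(cfg$seed, 50 + k))
    data.frame(node = base$node_ids[e], label = labels,
               delta = unname(vals[labels] - base_vals[labels]),
               sign = ifelse(vals[labels] > base_vals[labels], "+", "-"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
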