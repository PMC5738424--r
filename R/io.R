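#' Read a connectivity matrix from delimited text
#'
#' Expects a square matrix with node ids as header row and first column
#' (tab- or comma-separated, sniffed from the first line). Values must be
#' finite; asymmetries up to `tol` are averaged away, larger ones error.
#'
#' @param path file path.
#' @param tol symmetry tolerance (default 1e-8).
#' @return a [connectivity_matrix()].
#' @export
read_connectivity <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  df <- read.delim(path, sep = sep, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop(sprintf("matrix in %s is not square (%d x %d)", path, nrow(M), ncol(M)))
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value in %s at row '%s', column '%s'", path,
                 rownames(M)[bad[1]], colnames(M)[bad[2]]))
  }
  if (!identical(rownames(M), colnames(M)))
    stop("row and column node ids disagree in ", path)
  connectivity_matrix(M, node_ids = rownames(M), tol = tol)
}

#' Write a connectivity matrix as delimited text
#'
#' @param cm a [connectivity_matrix()].
#' @param path output path (tab-separated).
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(node_id = cm$node_ids, cm$weights, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read lesion patterns from a delimited table
#'
#' Accepts either a long table with columns `patient_id, node_id, lp` (and
#' optionally `total_volume`) or a wide matrix with patients as rows and
#' nodes as columns (first column = patient id).
#'
#' @param path file path.
#' @param format `"long"`, `"wide"` or `"auto"` (default: sniff from the
#'   header).
#' @return list of [lesion_pattern()] objects.
#' @export
read_lesion_table <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE)
  if (format == "auto")
    format <- if (all(c("patient_id", "node_id", "lp") %in% names(df)))
      "long" else "wide"
  if (format == "long") {
    nodes <- unique(df$node_id)
    lapply(split(df, df$patient_id), function(d) {
      lp <- setNames(numeric(length(nodes)), nodes)
      lp[as.character(d$node_id)] <- d$lp
      lesion_pattern(lp, patient_id = d$patient_id[1],
                     total_volume = if ("total_volume" %in% names(d))
                       d$total_volume[1] else NULL)
    })
  } else {
    ids <- as.character(df[[1]])
    has_vol <- "total_volume" %in% names(df)
    vols <- if (has_vol) df$total_volume else NULL
    X <- as.matrix(df[, setdiff(names(df)[-1], "total_volume"), drop = FALSE])
    lapply(seq_len(nrow(X)), function(i)
      lesion_pattern(X[i, ], patient_id = ids[i],
                     total_volume = if (has_vol) vols[i] else NULL))
  }
}

#' Write lesion patterns as a wide delimited table
#'
#' @param patterns list of [lesion_pattern()] objects.
#' @param path output path (tab-separated).
#' @export
write_lesion_table <- function(patterns, path) {
  X <- do.call(rbind, lapply(patterns, function(p) p$lp))
  df <- data.frame(patient_id = vapply(patterns, `[[`, character(1),
                                       "patient_id"),
                   X,
                   total_volume = vapply(patterns, `[[`, numeric(1),
                                         "total_volume"),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lesion mask / parcellation NIfTI pair
#'
#' Both images must be 3-D integer-labelled volumes on the same grid with the
#' same affine; mismatches are an error (no resampling is performed).
#'
#' @param mask_path path to the lesion mask (nonzero = lesioned).
#' @param parcellation_path path to the parcellation volume.
#' @return list with elements `mask` and `parcellation` (RNifti images).
#' @export
read_nifti_pair <- function(mask_path, parcellation_path) {
  mask <- RNifti::readNifti(mask_path)
  parc <- RNifti::readNifti(parcellation_path)
  check_grid_match(mask, parc)
  list(mask = mask, parcellation = parc)
}

#' Write a synthetic cohort to disk
#'
#' Exports the per-patient connectivity matrices, the wide lesion table, the
#' healthy base connectome and the ground-truth table in the same delimited
#' formats the pipeline reads back.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_connectivity(cohort$base, file.path(out_dir, "healthy_base.tsv"))
  mdir <- file.path(out_dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  for (i in seq_along(cohort$matrices))
    write_connectivity(cohort$matrices[[i]],
                       file.path(mdir, sprintf("%s.tsv",
                                               cohort$patterns[[i]]$patient_id)))
  write_lesion_table(cohort$patterns, file.path(out_dir, "lesions.tsv"))
  if (!is.null(cohort$ground_truth))
    write.table(cohort$ground_truth, file.path(out_dir, "ground_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read and validate a run configuration file
#'
#' Flat YAML keys: `labels` (subset of sigma/net_gE/net_locE), `sparsity` or
#' `auc_range` + `auc_step`, `n_random`, `n_perm`, `covariates`, `seed`,
#' `out_dir`, plus input paths (`matrix_dir`, `lesion_table`).
#'
#' @param path YAML file path.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(labels = c("sigma", "net_gE", "net_locE"),
                   sparsity = 0.15, auc_range = NULL, auc_step = 0.01,
                   n_random = 100, n_perm = 1000,
                   covariates = character(0), seed = 1, out_dir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  bad <- setdiff(cfg$labels, c("sigma", "net_gE", "net_locE"))
  if (length(bad) > 0)
    stop("unknown labels in config: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$auc_range)) {
    if (length(cfg$auc_range) != 2 || any(cfg$auc_range <= 0) ||
        any(cfg$auc_range > 1) || diff(cfg$auc_range) <= 0)
      stop("auc_range must be an increasing pair within (0, 1]")
  } else if (cfg$sparsity <= 0 || cfg$sparsity > 1) {
    stop("sparsity must lie in (0, 1]")
  }
  structure(cfg, class = "run_config")
}

#' Write the standard report files for a set of lesion models
#'
#' Writes five files into `out_dir`: per-patient predictions
#' (`predictions.tsv`), per-model accuracy and permutation P
#' (`model_summary.tsv`), the unthresholded weight table (`weights.tsv`), the
#' significant-hub table with effect classes (`lesion_hubs.tsv`), and a YAML
#' run manifest echoing the configuration, seeds and package version
#' (`manifest.yaml`).
#'
#' @param results named list of [lesion_model()] fits.
#' @param hub_table a [classify_lesion_hubs()] table (may have zero rows).
#' @param out_dir output directory (created if missing).
#' @param config optional configuration list echoed into the manifest.
#' @return invisibly, a named character vector of the files written.
#' @export
write_report <- function(results, hub_table, out_dir, config = NULL) {
  stopifnot(is.list(results), length(results) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(results)))
    names(results) <- vapply(results, `[[`, character(1), "label_name")
  pred <- do.call(rbind, lapply(names(results), function(nm) {
    f <- results[[nm]]
    data.frame(model = nm,
               patient_id = f$patient_ids %||% seq_along(f$actual),
               actual = f$actual, predicted = f$predicted,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(names(results), function(nm) {
    f <- results[[nm]]
    data.frame(model = nm, n = length(f$actual),
               accuracy_r = f$accuracy_r, p_value = f$p_value,
               n_perm = f$n_perm,
               n_significant_features = sum(f$features$significant),
               stringsAsFactors = FALSE)
  }))
  wts <- do.call(rbind, lapply(names(results), function(nm)
    cbind(model = nm, results[[nm]]$features)))
  files <- c(predictions = file.path(out_dir, "predictions.tsv"),
             model_summary = file.path(out_dir, "model_summary.tsv"),
             weights = file.path(out_dir, "weights.tsv"),
             lesion_hubs = file.path(out_dir, "lesion_hubs.tsv"),
             manifest = file.path(out_dir, "manifest.yaml"))
  write.table(pred, files["predictions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(summ, files["model_summary"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(wts, files["weights"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(hub_table), files["lesion_hubs"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(package = "lesionhub",
                   version = as.character(packageVersion("lesionhub")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seeds = lapply(results, function(f) f$seed),
                   models = lapply(results, function(f)
                     list(label = f$label_name, n_perm = f$n_perm,
                          cost = f$cost, epsilon = f$epsilon)),
                   config = config)
  yaml::write_yaml(manifest, files["manifest"])
  invisible(files)
}
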