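#' Lesion pattern for one patient
#'
#' Per-node lesion fractions (the lesion percentage Lp of each parcel, in
#' `[0, 1]`) plus the total lesion volume.
#'
#' @param lp named numeric vector of per-node lesion fractions.
#' @param patient_id patient identifier.
#' @param total_volume total lesioned volume (voxel count or mm^3); defaults
#'   to `sum(lp)` when no voxel bookkeeping is available.
#' @return object of class `lesion_pattern`.
#' @export
lesion_pattern <- function(lp, patient_id = NA_character_, total_volume = NULL) {
  lp <- unlist(lp)
  if (any(lp < 0 | lp > 1)) stop("lesion fractions must lie in [0, 1]")
  if (is.null(names(lp))) names(lp) <- paste0("n", seq_along(lp))
  if (is.null(total_volume)) total_volume <- sum(lp)
  if (total_volume < 0) stop("total_volume must be non-negative")
  structure(list(patient_id = as.character(patient_id),
                 lp = lp, total_volume = as.numeric(total_volume)),
            class = "lesion_pattern")
}

#' @export
print.lesion_pattern <- function(x, ...) {
  cat(sprintf("<lesion_pattern> %s: %d/%d nodes lesioned, max Lp %.2f, volume %.1f\n",
              x$patient_id, sum(x$lp > 0), length(x$lp), max(x$lp),
              x$total_volume))
  invisible(x)
}

#' Lesion percentages from a mask and a parcellation
#'
#' For each parcel of an integer-labelled parcellation volume, the fraction
#' of its voxels overlapped by the (nonzero) lesion mask. The two volumes
#' must share grid dimensions and affine; no resampling is performed.
#'
#' @param lesion_mask 3-D array or NIfTI image (nonzero = lesioned).
#' @param parcellation 3-D array or NIfTI image of integer parcel labels
#'   (0 = background).
#' @param patient_id identifier stored in the result.
#' @param parcel_labels optional integer vector of the labels the
#'   parcellation is expected to contain; parcels with no voxels are an
#'   error. Defaults to the labels present in the volume.
#' @return a [lesion_pattern()] whose names are the parcel labels and whose
#'   `total_volume` is the total lesioned-voxel count.
#' @export
compute_lesion_percentages <- function(lesion_mask, parcellation,
                                       patient_id = NA_character_,
                                       parcel_labels = NULL) {
  check_grid_match(lesion_mask, parcellation)
  mask <- as.array(lesion_mask) != 0
  parc <- as.integer(round(as.array(parcellation)))
  labels <- if (is.null(parcel_labels)) sort(unique(parc[parc > 0]))
            else sort(as.integer(parcel_labels))
  if (length(labels) == 0) stop("parcellation contains no nonzero labels")
  parc_f <- factor(parc, levels = labels)
  sizes <- tabulate(parc_f, nbins = length(labels))
  if (any(sizes == 0))
    stop("empty parcel(s): ", paste(labels[sizes == 0], collapse = ", "))
  lesioned <- tabulate(parc_f[as.vector(mask)], nbins = length(labels))
  lesion_pattern(setNames(lesioned / sizes, as.character(labels)),
                 patient_id = patient_id, total_volume = sum(mask))
}

check_grid_match <- function(a, b) {
  da <- dim(as.array(a)); db <- dim(as.array(b))
  if (length(da) != 3 || length(db) != 3)
    stop("mask and parcellation must be 3-D volumes")
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s vs %s", paste(da, collapse = "x"),
                 paste(db, collapse = "x")))
  xa <- try(RNifti::xform(a), silent = TRUE)
  xb <- try(RNifti::xform(b), silent = TRUE)
  if (!inherits(xa, "try-error") && !inherits(xb, "try-error") &&
      max(abs(unclass(xa) - unclass(xb))) > 1e-4)
    stop("affine mismatch between mask and parcellation (no resampling is done)")
  invisible(TRUE)
}

#' Assemble the SVR feature matrix from lesion patterns
#'
#' Stacks per-node lesion fractions into a patients x nodes matrix, drops
#' node features that are zero in every patient (recording them), and
#' optionally appends covariate columns (total lesion volume, age, time post
#' onset), each min-max scaled to `[0, 1]` so they stay commensurate with the
#' lesion-fraction features.
#'
#' @param patterns list of [lesion_pattern()] objects with identical node
#'   sets.
#' @param covariates subset of `c("total_volume", "age", "time_post_onset")`.
#' @param covariate_data data.frame with one row per patient supplying `age`
#'   and/or `time_post_onset` when requested.
#' @return object of class `feature_matrix`: list with `X`, `patient_ids`,
#'   `feature_ids`, `dropped_features`.
#' @export
assemble_features <- function(patterns, covariates = character(0),
                              covariate_data = NULL) {
  if (length(patterns) < 3) stop("need at least 3 patients")
  if (length(covariates) > 0)
    covariates <- match.arg(covariates,
                            c("total_volume", "age", "time_post_onset"),
                            several.ok = TRUE)
  nodes <- names(patterns[[1]]$lp)
  for (k in seq_along(patterns))
    if (!identical(names(patterns[[k]]$lp), nodes))
      stop(sprintf("patient %d has a different node set", k))
  X <- do.call(rbind, lapply(patterns, function(p) p$lp))
  patient_ids <- vapply(patterns, function(p) p$patient_id, character(1))
  if (anyNA(patient_ids) || anyDuplicated(patient_ids))
    patient_ids <- paste0("p", seq_along(patterns))
  rownames(X) <- patient_ids
  never <- colSums(X > 0) == 0
  dropped <- nodes[never]
  X <- X[, !never, drop = FALSE]
  if (ncol(X) == 0) stop("all node features are zero in every patient")
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  for (cv in covariates) {
    vals <- if (cv == "total_volume")
      vapply(patterns, function(p) p$total_volume, numeric(1))
    else {
      if (is.null(covariate_data) || is.null(covariate_data[[cv]]))
        stop(sprintf("covariate '%s' requested but not supplied in covariate_data", cv))
      as.numeric(covariate_data[[cv]])
    }
    X <- cbind(X, setNames(data.frame(minmax(vals)), cv))
    X <- as.matrix(X)
  }
  structure(list(X = X, patient_ids = patient_ids,
                 feature_ids = colnames(X), dropped_features = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features (%d never-lesioned nodes dropped)\n",
              nrow(x$X), ncol(x$X), length(x$dropped_features)))
  invisible(x)
}
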