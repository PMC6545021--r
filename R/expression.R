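#' Counts-per-million normalisation
#'
#' Scales each cell's counts to counts per million. By default the library
#' size of a cell is the column sum of the repeat count matrix itself, which
#' keeps the analysis self-contained; an externally supplied vector of
#' total-mapped-read counts can be passed instead when available (e.g. totals
#' that include gene-derived reads).
#'
#' @param counts feature-by-cell count matrix (fractional values allowed).
#' @param library_sizes optional named numeric vector of per-cell totals;
#'   names must cover `colnames(counts)`.
#' @return a `cpm_matrix`: numeric matrix with attributes `log2 = FALSE` and
#'   `lib_sizes`.
#' @export
compute_cpm <- function(counts, library_sizes = NULL) {
  .assert(is.matrix(counts) && is.numeric(counts), "counts must be a numeric matrix")
  if (is.null(library_sizes)) {
    lib <- colSums(counts)
  } else {
    .assert(all(colnames(counts) %in% names(library_sizes)),
            "library_sizes missing cell(s): %s",
            paste(setdiff(colnames(counts), names(library_sizes)), collapse = ", "))
    lib <- library_sizes[colnames(counts)]
  }
  zero <- which(lib <= 0)
  if (length(zero) > 0L)
    .halt("zero library size for cell(s): %s",
          paste(colnames(counts)[zero], collapse = ", "))
  cpm <- sweep(counts, 2L, lib, `/`) * 1e6
  structure(cpm, log2 = FALSE, lib_sizes = lib, class = c("cpm_matrix", "matrix", "array"))
}

#' @export
print.cpm_matrix <- function(x, ...) {
  cat(sprintf("cpm_matrix: %d features x %d cells (%s scale)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "log2"))) "log2(CPM+1)" else "CPM"))
  invisible(x)
}

.is_log2 <- function(cpm) isTRUE(attr(cpm, "log2"))

#' log2(CPM + 1) transform
#'
#' @param cpm a `cpm_matrix` on the linear CPM scale.
#' @return the matrix with values `log2(cpm + 1)` and the `log2` flag set;
#'   applying the transform twice is an error.
#' @export
log2_cpm <- function(cpm) {
  if (.is_log2(cpm)) .halt("matrix is already log2-transformed")
  out <- log2(unclass(cpm) + 1)
  structure(out, log2 = TRUE, lib_sizes = attr(cpm, "lib_sizes"),
            class = c("cpm_matrix", "matrix", "array"))
}

#' Stage-wise repeat retention filter
#'
#' A repeat is retained when there exists at least one developmental stage in
#' which every single cell of that stage expresses it at or above the CPM
#' threshold. This is a noise filter: a repeat must be reliably detected in
#' all cells of some stage, not merely sporadically across the dataset.
#'
#' @param cpm `cpm_matrix` on the linear scale.
#' @param meta cell metadata (`cell_id`, `stage`).
#' @param threshold CPM cutoff (default 1).
#' @return character vector of retained repeat names.
#' @export
filter_repeats_by_stage <- function(cpm, meta, threshold = 1) {
  .assert(!.is_log2(cpm), "filter operates on linear CPM, not log2")
  .assert(all(colnames(cpm) %in% meta$cell_id),
          "cells in matrix missing from metadata")
  groups <- .cells_by_stage(meta[meta$cell_id %in% colnames(cpm), ])
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty) > 0L) .halt("stage with zero cells: %s", empty[1L])
  pass_any <- rep(FALSE, nrow(cpm))
  for (cells in groups) {
    pass_any <- pass_any |
      (rowSums(cpm[, cells, drop = FALSE] >= threshold) == length(cells))
  }
  rownames(cpm)[pass_any]
}

#' Gene TPM retention filter
#'
#' Drops genes whose stage-mean TPM is below the threshold in every
#' developmental stage; a gene reaching the threshold in any one stage is
#' kept. The comparison is at stage level (stage means), recorded in the
#' result's `"rule"` attribute.
#'
#' @param tpm gene-by-cell TPM matrix.
#' @param meta cell metadata.
#' @param threshold TPM cutoff (default 1).
#' @return character vector of retained gene ids.
#' @export
filter_genes_by_tpm <- function(tpm, meta, threshold = 1) {
  groups <- .cells_by_stage(meta[meta$cell_id %in% colnames(tpm), ])
  stage_means <- vapply(groups, function(cells)
    rowMeans(tpm[, cells, drop = FALSE]), numeric(nrow(tpm)))
  if (nrow(tpm) == 1L) stage_means <- matrix(stage_means, nrow = 1L)
  keep <- apply(stage_means >= threshold, 1L, any)
  structure(rownames(tpm)[keep], rule = "stage_mean >= threshold in >= 1 stage")
}

#' Per-stage coefficient of variation
#'
#' CV = sample standard deviation / mean over all single cells of a stage,
#' computed per feature. Undefined (NA) when the stage mean is zero; zero-mean
#' values are never silently treated as zeros of the CV.
#'
#' @param expr feature-by-cell matrix (any scale).
#' @param meta cell metadata.
#' @return long data.frame `feature`, `stage`, `cv`.
#' @export
stage_cv <- function(expr, meta) {
  groups <- .cells_by_stage(meta[meta$cell_id %in% colnames(expr), ])
  out <- lapply(names(groups), function(s) {
    sub <- expr[, groups[[s]], drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    data.frame(feature = rownames(expr), stage = s,
               cv = ifelse(mu == 0, NA_real_, sdv / mu),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Z-score a vector of per-stage means
#'
#' `z_s = (mean_s - mean over stages) / (sample sd over stages)`. A constant
#' profile has no variance to standardise and yields all zeros.
#'
#' @param stage_means numeric vector of per-stage mean expression values.
#' @return numeric vector of z-scores, same length and names.
#' @export
zscore_profile <- function(stage_means) {
  .assert(length(stage_means) >= 2L, "z-score profile requires >= 2 stages")
  s <- stats::sd(stage_means)
  if (s == 0 || is.na(s)) return(stage_means * 0)
  (stage_means - mean(stage_means)) / s
}

#' Per-stage expression profiles with z-scores
#'
#' For each feature: per-stage mean of the supplied (typically log2(CPM+1))
#' values, the standard error of that mean, and the across-stage z-score of
#' the stage means. This is the table behind stage-profile heat maps.
#'
#' @param expr feature-by-cell matrix, conventionally log2(CPM+1).
#' @param meta cell metadata.
#' @return long data.frame `feature`, `stage`, `mean`, `sem`, `z`.
#' @export
stage_profiles <- function(expr, meta) {
  groups <- .cells_by_stage(meta[meta$cell_id %in% colnames(expr), ])
  means <- vapply(groups, function(cells)
    rowMeans(expr[, cells, drop = FALSE]), numeric(nrow(expr)))
  sems <- vapply(groups, function(cells) {
    sub <- expr[, cells, drop = FALSE]
    if (length(cells) < 2L) return(rep(NA_real_, nrow(expr)))
    apply(sub, 1L, stats::sd) / sqrt(length(cells))
  }, numeric(nrow(expr)))
  if (nrow(expr) == 1L) {
    means <- matrix(means, nrow = 1L, dimnames = list(rownames(expr), names(groups)))
    sems <- matrix(sems, nrow = 1L, dimnames = list(rownames(expr), names(groups)))
  }
  z <- t(apply(means, 1L, zscore_profile))
  data.frame(feature = rep(rownames(expr), times = ncol(means)),
             stage = rep(colnames(means), each = nrow(means)),
             mean = as.vector(means), sem = as.vector(sems), z = as.vector(z),
             stringsAsFactors = FALSE)
}

#' Repeat-derived read percentage per cell
#'
#' `100 * R / (R + G)` where `R` is the cell's total repeat-derived count and
#' `G` its total gene-derived count; undefined when both totals are zero.
#'
#' @param repeat_totals named numeric vector of per-cell repeat count totals.
#' @param gene_totals named numeric vector of per-cell gene count totals
#'   (same cells).
#' @return named numeric vector of percentages (NA where R + G = 0).
#' @export
read_percentage <- function(repeat_totals, gene_totals) {
  .assert(all(names(repeat_totals) %in% names(gene_totals)),
          "cell sets differ between repeat and gene totals")
  g <- gene_totals[names(repeat_totals)]
  tot <- repeat_totals + g
  ifelse(tot == 0, NA_real_, 100 * repeat_totals / tot)
}

#' PCA of cells in expression space
#'
#' Standard centred (unscaled) principal component analysis of cells over
#' features, with a deterministic sign convention: each component is flipped
#' if necessary so that its largest-magnitude feature loading is positive.
#' Optionally restricts to the top-N most variable features first, as
#' single-cell PCA plotting functions conventionally do.
#'
#' @param expr feature-by-cell matrix (conventionally log2(CPM+1)).
#' @param n_components number of components to return.
#' @param n_top_variable optional count of most-variable features to use.
#' @return list with `coordinates` (cell x component matrix) and
#'   `explained_variance` (fraction per component).
#' @export
pca_coordinates <- function(expr, n_components = 2L, n_top_variable = NULL) {
  .assert(ncol(expr) >= 2L && nrow(expr) >= 2L, "PCA requires >= 2 cells and >= 2 features")
  if (!is.null(n_top_variable) && n_top_variable < nrow(expr)) {
    v <- apply(expr, 1L, stats::var)
    expr <- expr[order(v, decreasing = TRUE)[seq_len(n_top_variable)], , drop = FALSE]
  }
  .assert(nrow(expr) >= n_components,
          "fewer features (%d) than requested components (%d)", nrow(expr), n_components)
  fit <- stats::prcomp(t(unclass(expr)), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  .assert(k >= n_components, "input rank too low for %d components", n_components)
  flip <- vapply(seq_len(k), function(j) {
    load <- fit$rotation[, j]
    sign(load[which.max(abs(load))])
  }, numeric(1L))
  coords <- sweep(fit$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)])
}

#' Repeat-class by stage mean expression
#'
#' Pools all (repeat, cell) values of a class at a stage and reports their
#' mean and standard error of the mean. Classes with no member repeat in the
#' matrix are omitted.
#'
#' @param expr repeat-by-cell matrix, conventionally log2(CPM+1).
#' @param meta cell metadata.
#' @param classes named character vector mapping repeat name -> repeat class.
#' @return data.frame `repeat_class`, `stage`, `mean`, `sem`, `n`.
#' @export
class_stage_means <- function(expr, meta, classes) {
  .assert(all(rownames(expr) %in% names(classes)),
          "repeat(s) missing from class map")
  groups <- .cells_by_stage(meta[meta$cell_id %in% colnames(expr), ])
  cls <- classes[rownames(expr)]
  out <- list()
  for (cl in unique(cls)) {
    sub <- expr[cls == cl, , drop = FALSE]
    for (s in names(groups)) {
      vals <- as.vector(sub[, groups[[s]], drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        repeat_class = cl, stage = s, mean = mean(vals),
        sem = if (length(vals) >= 2L) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
        n = length(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
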