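#' Module eigengene
#'
#' The eigengene of a co-expression module is the first principal component
#' of its gene-by-cell expression submatrix, with genes standardised first so
#' that highly expressed genes do not dominate. PCA leaves the sign of a
#' component arbitrary; here the sign is fixed so that the eigengene
#' correlates non-negatively with the module's mean expression profile,
#' making downstream stage correlations reproducible.
#'
#' @param expr gene-by-cell expression submatrix of one module
#'   (>= 2 genes, >= 2 cells).
#' @return named numeric vector of per-cell scores, centred to mean 0.
#' @export
compute_eigengene <- function(expr) {
  .assert(nrow(expr) >= 2L && ncol(expr) >= 2L,
          "eigengene requires >= 2 genes and >= 2 cells")
  sds <- apply(expr, 1L, stats::sd)
  if (all(sds == 0)) .halt("constant module submatrix: eigengene undefined")
  z <- (expr[sds > 0, , drop = FALSE] - rowMeans(expr[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  fit <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  eg <- fit$x[, 1L]
  ref <- colMeans(expr)
  if (stats::sd(ref) > 0 && stats::cor(eg, ref) < 0) eg <- -eg
  eg - mean(eg)
}

#' Stage specificity of a per-cell profile
#'
#' Pearson correlation between a per-cell score (eigengene or single-gene
#' profile) and the 0/1 indicator of membership in one stage, with the
#' p-value from the two-sided t reference distribution on n - 2 df.
#'
#' @param score named numeric vector of per-cell values.
#' @param meta cell metadata covering the score's cells.
#' @param stage stage label to test.
#' @return list with `r` and `p` (both NA for a constant score or a stage
#'   indicator without variation).
#' @export
stage_specificity <- function(score, meta, stage) {
  .assert(length(score) >= 3L, "stage specificity requires >= 3 cells")
  .assert(all(names(score) %in% meta$cell_id), "cells missing from metadata")
  ind <- as.numeric(meta$stage[match(names(score), meta$cell_id)] == stage)
  if (stats::sd(score) == 0 || stats::sd(ind) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(score, ind, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# r for every gene (rows) against every stage indicator at once; returns the
# r matrix and matching two-sided t-test p matrix
.stage_cor_matrix <- function(expr, meta) {
  stages <- levels(droplevels(meta$stage[match(colnames(expr), meta$cell_id)]))
  ind <- vapply(stages, function(s)
    as.numeric(meta$stage[match(colnames(expr), meta$cell_id)] == s),
    numeric(ncol(expr)))
  r <- suppressWarnings(stats::cor(t(unclass(expr)), ind))
  n <- ncol(expr)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, stages = stages)
}

#' Assign genes to stage-specific modules
#'
#' A deliberately simple stage-specificity assigner: each gene is correlated
#' with every stage's 0/1 indicator, assigned to the stage maximising r
#' (earliest developmental stage on ties), and kept only when that best
#' correlation passes `r > r_min` and `p < p_max`. Stage groups smaller than
#' `min_module_size` are dropped; all other genes stay unassigned. Module
#' labels are colour-style strings, one colour per stage, following the
#' labelling convention of co-expression network tools. Genuine network
#' module assignments produced externally can be substituted via
#' [import_modules()].
#'
#' @param expr gene-by-cell expression matrix (filtered genes).
#' @param meta cell metadata.
#' @param min_module_size minimum genes per retained module (default 30).
#' @param r_min correlation threshold (default 0.50, exclusive).
#' @param p_max p-value threshold (default 1e-3, exclusive).
#' @return data.frame `gene_id`, `module_label`, `stage`, `r`, `p` with one
#'   row per assigned gene.
#' @export
assign_stage_modules <- function(expr, meta, min_module_size = 30L,
                                 r_min = 0.50, p_max = 1e-3) {
  cm <- .stage_cor_matrix(expr, meta)
  r <- cm$r; p <- cm$p
  r[is.na(r)] <- -Inf
  best <- apply(r, 1L, which.max)  # which.max takes the first (earliest stage) on ties
  idx <- cbind(seq_len(nrow(r)), best)
  best_r <- r[idx]; best_p <- p[idx]
  keep <- is.finite(best_r) & best_r > r_min & !is.na(best_p) & best_p < p_max
  out <- data.frame(gene_id = rownames(expr)[keep],
                    stage = cm$stages[best[keep]],
                    r = best_r[keep], p = best_p[keep],
                    stringsAsFactors = FALSE)
  tab <- table(out$stage)
  out <- out[out$stage %in% names(tab)[tab >= min_module_size], , drop = FALSE]
  out$module_label <- .stage_colour(out$stage)
  rownames(out) <- NULL
  out[, c("gene_id", "module_label", "stage", "r", "p")]
}

# one colour per stage, WGCNA-style palette
.stage_colour <- function(stage) {
  pal <- c(oocyte = "turquoise", zygote = "blue", `2cell` = "brown",
           `4cell` = "yellow", `8cell` = "green", morula = "red",
           late_blastocyst = "black", ESC_P0 = "pink", ESC_P10 = "magenta")
  unname(pal[as.character(stage)])
}

#' Merge modules with highly correlated eigengenes
#'
#' Modules whose eigengenes correlate at or above `r_threshold` are merged;
#' merging is by transitive closure (connected components of the
#' correlation-threshold graph), and each merged module's eigengene is
#' recomputed from the union of its genes. The threshold applies to r itself,
#' not |r|: anticorrelated modules are never merged.
#'
#' @param modules data.frame `gene_id`, `module_label` (as from
#'   [assign_stage_modules()] or [import_modules()]).
#' @param expr gene-by-cell expression matrix covering the module genes.
#' @param r_threshold merge threshold on eigengene correlation (default 0.7).
#' @return list with `modules` (reassigned gene table; merged labels joined
#'   with `+`) and `eigengenes` (list of per-cell score vectors by label).
#' @export
merge_modules <- function(modules, expr, r_threshold = 0.7) {
  .assert(nrow(modules) > 0L, "no modules to merge")
  labels <- unique(modules$module_label)
  eg <- lapply(labels, function(l)
    compute_eigengene(expr[modules$gene_id[modules$module_label == l], , drop = FALSE]))
  names(eg) <- labels
  comp <- seq_along(labels)
  if (length(labels) > 1L) {
    cmat <- stats::cor(do.call(cbind, eg))
    # union-find over pairs meeting the threshold gives the transitive closure
    for (i in seq_along(labels)) for (j in seq_len(i - 1L)) {
      if (cmat[i, j] >= r_threshold) {
        ci <- comp[i]; cj <- comp[j]
        comp[comp == ci] <- cj
      }
    }
  }
  out <- modules
  eg_out <- list()
  for (cid in unique(comp)) {
    members <- labels[comp == cid]
    new_label <- paste(sort(members), collapse = "+")
    sel <- modules$module_label %in% members
    out$module_label[sel] <- new_label
    eg_out[[new_label]] <-
      compute_eigengene(expr[modules$gene_id[sel], , drop = FALSE])
  }
  list(modules = out, eigengenes = eg_out)
}

#' Import an externally produced module assignment
#'
#' Reads a TSV with header columns `gene_id`, `module_label` and optionally
#' `stage`, e.g. the gene lists exported by a full weighted co-expression
#' network analysis. A gene listed twice with conflicting modules is an
#' error; exact duplicate rows are collapsed.
#'
#' @param path input path.
#' @return data.frame `gene_id`, `module_label` (+ `stage` when present).
#' @export
import_modules <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "module_label")
  .assert(all(need %in% names(df)),
          "module file missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  df <- unique(df)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0L)
    .halt("gene(s) assigned to more than one module: %s",
          paste(unique(dup), collapse = ", "))
  if ("stage" %in% names(df)) df$stage <- as.character(df$stage)
  df
}

#' Export a module assignment
#'
#' Round-trips with [import_modules()].
#'
#' @param modules data.frame with `gene_id`, `module_label` (+ optional
#'   `stage`, `r`, `p`).
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
export_modules <- function(modules, path, seed = NULL) {
  write_result_tsv(modules, path, seed = seed)
}
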