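#' Pearson correlation with t-based p-value
#'
#' Pairwise-complete Pearson correlation; the p-value comes from the
#' two-sided t reference distribution with n - 2 df, the conventional test
#' behind `cor.test`. Returns missing r for constant vectors or fewer than 3
#' complete pairs.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, and `n` (complete pairs used).
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || .sd0(x[ok]) == 0 || .sd0(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Repeat-to-module-gene correlations
#'
#' For each selected repeat and each gene of its associated module, the
#' Pearson correlation of expression across all single cells of all stages.
#' By default only repeats in the strict enrichment tier (`ES > 3.5`,
#' `p < 1e-3`) are correlated, mirroring the selection used for
#' repeat-nearby-gene follow-up; pass `pairs` to override.
#'
#' @param repeat_expr repeat-by-cell expression matrix (log2(CPM+1)).
#' @param gene_expr gene-by-cell expression matrix on the same cells.
#' @param modules module assignment (`gene_id`, `module_label`).
#' @param enrichment output of [enrich_repeats()]; its `fig_tier` flag
#'   selects (repeat, module) pairs.
#' @param pairs optional data.frame `repeat_name`, `module` overriding the
#'   tier selection.
#' @return data.frame `repeat_name`, `module`, `gene_id`, `r`, `p`, `n`.
#' @export
repeat_module_correlations <- function(repeat_expr, gene_expr, modules,
                                       enrichment = NULL, pairs = NULL) {
  if (is.null(pairs)) {
    .assert(!is.null(enrichment), "supply either enrichment results or pairs")
    pairs <- enrichment[enrichment$fig_tier, c("repeat_name", "module"),
                        drop = FALSE]
  }
  shared <- intersect(colnames(repeat_expr), colnames(gene_expr))
  .assert(length(shared) >= 3L, "need >= 3 shared cells")
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    rn <- pairs$repeat_name[k]
    mod <- pairs$module[k]
    if (!(rn %in% rownames(repeat_expr))) next
    gids <- intersect(modules$gene_id[modules$module_label == mod],
                      rownames(gene_expr))
    rx <- repeat_expr[rn, shared]
    for (gid in gids) {
      ct <- pearson_cor(rx, gene_expr[gid, shared])
      out[[length(out) + 1L]] <- data.frame(
        repeat_name = rn, module = mod, gene_id = gid,
        r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(repeat_name = character(0), module = character(0),
                      gene_id = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Class-level methylation-expression correlation by stage
#'
#' For each (repeat class, stage) cell: the Pearson correlation, over the
#' class's member repeats, of per-repeat stage-mean expression against
#' per-repeat stage-mean methylation. Stage means are used because the
#' expression and methylation datasets come from different embryos and are
#' unpaired at cell level. Cells with fewer than `min_repeats` repeats having
#' both quantities are reported missing.
#'
#' @param expr_stage_means data.frame `repeat_name`, `stage`, `mean`
#'   (expression), e.g. from [stage_profiles()] with `feature` renamed.
#' @param meth_stage_means data.frame `repeat_name`, `stage`, `mean`
#'   (methylation percent).
#' @param classes named character vector repeat name -> class.
#' @param min_repeats minimum paired repeats per cell (default 3).
#' @return data.frame `repeat_class`, `stage`, `r`, `p`, `n` (the heat-map
#'   table; `r`/`p` NA where undefined).
#' @export
class_methylation_expression_correlation <- function(expr_stage_means,
                                                     meth_stage_means,
                                                     classes,
                                                     min_repeats = 3L) {
  merged <- merge(expr_stage_means, meth_stage_means,
                  by = c("repeat_name", "stage"),
                  suffixes = c("_expr", "_meth"))
  merged$repeat_class <- unname(classes[merged$repeat_name])
  .assert(!anyNA(merged$repeat_class), "class map missing for some repeats")
  out <- list()
  for (cl in sort(unique(merged$repeat_class))) {
    for (s in unique(merged$stage)) {
      sub <- merged[merged$repeat_class == cl & merged$stage == s, ]
      if (nrow(sub) < min_repeats) {
        ct <- list(r = NA_real_, p = NA_real_, n = nrow(sub))
      } else {
        ct <- pearson_cor(sub$mean_expr, sub$mean_meth)
      }
      out[[length(out) + 1L]] <- data.frame(
        repeat_class = cl, stage = s, r = ct$r, p = ct$p, n = ct$n,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way ANOVA with Tukey HSD stage contrasts
#'
#' Compares a measurement (CVs, methylation percentages, ...) across
#' developmental stages: one-way ANOVA F and p, followed by Tukey's honestly
#' significant difference test for every stage pair, flagged at `alpha_adj`
#' on the adjusted p. Groups with fewer than 2 values are excluded with a
#' warning.
#'
#' @param values numeric vector.
#' @param groups group (stage) label per value.
#' @param alpha_adj significance threshold on Tukey-adjusted p
#'   (default 0.001).
#' @return list with `anova_F`, `anova_p`, and `contrasts` (data.frame
#'   `contrast`, `diff`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(values, groups, alpha_adj = 0.001) {
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L) {
    warning(sprintf("excluding group(s) with < 2 values: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  .assert(length(unique(groups)) >= 2L, "ANOVA requires >= 2 groups")
  df <- data.frame(v = values, g = factor(groups))
  fit <- stats::aov(v ~ g, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$g
  contrasts <- data.frame(contrast = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          significant = tk[, "p adj"] < alpha_adj,
                          stringsAsFactors = FALSE)
  rownames(contrasts) <- NULL
  list(anova_F = an[["F value"]][1L], anova_p = an[["Pr(>F)"]][1L],
       contrasts = contrasts)
}
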