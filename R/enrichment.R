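#' Promoter window upstream of a TSS
#'
#' Builds the `width`-bp window immediately upstream of each gene's TSS, in
#' transcription direction, as 0-based half-open intervals:
#' `[max(0, tss - width), tss)` on the + strand and
#' `[tss + 1, tss + 1 + width)` on the - strand, clipped to the chromosome
#' end when `chrom_lengths` is given. The TSS base itself is excluded in both
#' orientations (the window is strictly upstream). A strand-ignorant mode
#' (`[tss - width, tss)` regardless of strand) is available for sensitivity
#' checks.
#'
#' @param genes data.frame `gene_id`, `chrom`, `tss`, `strand`.
#' @param width window width in bp (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @param strand_aware honour strand (default TRUE).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_windows <- function(genes, width = 2000L, chrom_lengths = NULL,
                             strand_aware = TRUE) {
  .assert(all(genes$tss >= 0L), "negative TSS")
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[genes$chrom]
    .assert(!anyNA(len), "chromosome length missing for some genes")
    if (any(genes$tss >= len))
      .halt("TSS beyond chromosome end for gene %s",
            genes$gene_id[which(genes$tss >= len)[1L]])
  }
  minus <- strand_aware & genes$strand == "-"
  start <- ifelse(minus, genes$tss + 1L, pmax(0L, genes$tss - width))
  end <- ifelse(minus, genes$tss + 1L + width, genes$tss)
  if (!is.null(chrom_lengths)) end <- pmin(end, chrom_lengths[genes$chrom])
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = genes$strand, stringsAsFactors = FALSE)
  out[out$end > out$start, , drop = FALSE]
}

#' Count repeat instances overlapping promoter windows
#'
#' An instance overlaps a window when their half-open intersection is at
#' least 1 bp. Counting is per distinct instance: an instance overlapping the
#' windows of two genes counts once towards the per-repeat instance count,
#' while the set of genes it touches is tracked separately for the
#' gene-association rule. A pair-counting mode (each (instance, window)
#' overlap counted) is available for comparison.
#'
#' @param windows promoter window data.frame (from [promoter_windows()]).
#' @param instances repeat instance data.frame.
#' @param count_mode `"instance"` (default, distinct instances) or `"pair"`.
#' @return list with `per_repeat` (data.frame `repeat_name`, `count`,
#'   `n_genes`), `total` (summed counts over all repeats), and `gene_sets`
#'   (list of associated gene ids by repeat name).
#' @export
count_window_repeats <- function(windows, instances,
                                 count_mode = c("instance", "pair")) {
  count_mode <- match.arg(count_mode)
  if (nrow(windows) == 0L || nrow(instances) == 0L) {
    return(list(per_repeat = data.frame(repeat_name = character(0),
                                        count = integer(0), n_genes = integer(0)),
                total = 0L, gene_sets = list()))
  }
  gr_w <- .as_granges(windows$chrom, windows$start, windows$end)
  gr_i <- .as_granges(instances$chrom, instances$start, instances$end)
  ov <- GenomicRanges::findOverlaps(gr_i, gr_w, minoverlap = 1L)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  rn <- instances$repeat_name[qi]
  gid <- windows$gene_id[si]
  gene_sets <- lapply(split(gid, rn), unique)
  if (count_mode == "instance") {
    hits <- unique(data.frame(rn = rn, qi = qi))
    counts <- table(hits$rn)
  } else {
    counts <- table(rn)
  }
  per_repeat <- data.frame(repeat_name = names(counts),
                           count = as.integer(counts),
                           n_genes = lengths(gene_sets)[names(counts)],
                           stringsAsFactors = FALSE)
  rownames(per_repeat) <- NULL
  list(per_repeat = per_repeat, total = sum(per_repeat$count),
       gene_sets = gene_sets)
}

#' Promoter repeat enrichment score
#'
#' `ES = (r / R) / (g / G)`: the ratio of a repeat's share of promoter-window
#' occurrences among module genes (`r` of `R`) to its share among all genes
#' (`g` of `G`). A repeat absent from module windows scores 0; a repeat
#' present in module windows but absent genome-wide is flagged infinite.
#'
#' @param r this repeat's count in module-gene windows.
#' @param R all repeats' count in module-gene windows (> 0).
#' @param g this repeat's count in all-gene windows.
#' @param G all repeats' count in all-gene windows (> 0).
#' @return the enrichment score (possibly `Inf`).
#' @export
enrichment_score <- function(r, R, g, G) {
  .assert(R > 0 && G > 0, "no repeats in windows: R and G must be > 0")
  .assert(r >= 0 && g >= 0 && r <= R && g <= G,
          "inconsistent enrichment counts (need 0 <= r <= R, 0 <= g <= G)")
  if (r == 0) return(0)
  if (g == 0) return(Inf)
  (r / R) / (g / G)
}

#' Fisher exact p-value for an enrichment table
#'
#' Two-sided Fisher's exact test on the contingency table
#' `[[r, R - r], [g - r, (G - g) - (R - r)]]` (this repeat vs all other
#' repeats, module windows vs remaining windows): the sum of hypergeometric
#' probabilities of all tables with the same margins that are no more
#' probable than the observed one.
#'
#' @param r,R,g,G counts as in [enrichment_score()].
#' @return two-sided p-value.
#' @export
fisher_pvalue <- function(r, R, g, G) {
  tab <- matrix(c(r, R - r, g - r, (G - g) - (R - r)), nrow = 2L, byrow = TRUE)
  if (any(tab < 0))
    .halt("inconsistent counts: derived contingency cell is negative")
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Full promoter enrichment analysis
#'
#' For every (repeat, module) pair: builds 2-kb upstream windows for the
#' module's genes and for all genes, counts repeat instances in each window
#' set, and computes the enrichment score, Fisher p-value, and the
#' gene-association count. Overlapping gene windows are not merged; each
#' gene's window is tested independently, and the distinct-instance rule
#' prevents double counting.
#'
#' @param genes all gene models (`gene_id`, `chrom`, `tss`, `strand`).
#' @param instances repeat instances.
#' @param modules module assignment (`gene_id`, `module_label`).
#' @param width upstream window width (default 2000).
#' @param chrom_lengths optional named chromosome lengths.
#' @param strand_aware honour gene strand when placing windows.
#' @param count_mode `"instance"` or `"pair"` (see [count_window_repeats()]).
#' @param min_genes,es_min,p_max significance rule thresholds (defaults 5,
#'   1.5, 1e-4); a second tier flag `fig_tier` marks `ES > 3.5, p < 1e-3`,
#'   the stricter selection used for repeat-gene correlation follow-up.
#' @return data.frame with columns `repeat_name`, `module`, `r`, `R`, `g`,
#'   `G`, `n_genes`, `ES`, `p`, `significant`, `fig_tier`.
#' @export
enrich_repeats <- function(genes, instances, modules, width = 2000L,
                           chrom_lengths = NULL, strand_aware = TRUE,
                           count_mode = "instance",
                           min_genes = 5L, es_min = 1.5, p_max = 1e-4) {
  all_w <- promoter_windows(genes, width, chrom_lengths, strand_aware)
  bg <- count_window_repeats(all_w, instances, count_mode)
  .assert(bg$total > 0, "no repeat instance overlaps any promoter window")
  g_map <- stats::setNames(bg$per_repeat$count, bg$per_repeat$repeat_name)
  out <- list()
  for (mod in unique(modules$module_label)) {
    mod_genes <- modules$gene_id[modules$module_label == mod]
    mod_w <- all_w[all_w$gene_id %in% mod_genes, , drop = FALSE]
    fg <- count_window_repeats(mod_w, instances, count_mode)
    if (fg$total == 0) next
    for (k in seq_len(nrow(fg$per_repeat))) {
      rn <- fg$per_repeat$repeat_name[k]
      r <- fg$per_repeat$count[k]
      g <- unname(g_map[rn])
      es <- enrichment_score(r, fg$total, g, bg$total)
      p <- fisher_pvalue(r, fg$total, g, bg$total)
      ng <- fg$per_repeat$n_genes[k]
      out[[length(out) + 1L]] <- data.frame(
        repeat_name = rn, module = mod, r = r, R = fg$total, g = g,
        G = bg$total, n_genes = ng, ES = es, p = p,
        significant = (ng >= min_genes && es >= es_min && p <= p_max),
        fig_tier = (ng >= min_genes && es > 3.5 && p < 1e-3),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(repeat_name = character(0), module = character(0),
                      r = integer(0), R = integer(0), g = integer(0),
                      G = integer(0), n_genes = integer(0), ES = numeric(0),
                      p = numeric(0), significant = logical(0),
                      fig_tier = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter enrichment results by the significance rule
#'
#' Keeps results with at least `min_genes` associated module genes,
#' `ES >= es_min` and `p <= p_max`.
#'
#' @param results output of [enrich_repeats()].
#' @param min_genes,es_min,p_max rule thresholds (defaults 5, 1.5, 1e-4).
#' @return the filtered data.frame.
#' @export
significant_enrichments <- function(results, min_genes = 5L, es_min = 1.5,
                                    p_max = 1e-4) {
  keep <- results$n_genes >= min_genes & results$ES >= es_min &
    results$p <= p_max
  results[keep, , drop = FALSE]
}
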