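#' CpG coverage filter
#'
#' Removes CpG records supported by fewer than `min_coverage` total reads;
#' a record at exactly the threshold is kept (at-least semantics). The number
#' of records removed is attached as the `"n_removed"` attribute so callers
#' can audit that no low-coverage record ever reaches a methylation
#' percentage.
#'
#' @param records validated CpG record data.frame.
#' @param min_coverage minimum total reads (default 5).
#' @return the filtered data.frame.
#' @export
filter_cpgs <- function(records, min_coverage = 5L) {
  keep <- records$total_reads >= min_coverage
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_removed = sum(!keep))
}

#' Assign CpG records to overlapping repeat instances
#'
#' A CpG at position `p` belongs to every repeat instance with
#' `start <= p < end` (half-open inclusion). CpGs inside overlapping
#' instances of different repeat types contribute to each type
#' independently; there is no arbitration.
#'
#' @param records CpG record data.frame.
#' @param instances repeat instance data.frame.
#' @return data.frame of (record, repeat) assignments: the record columns
#'   plus `repeat_name`.
#' @export
assign_cpgs_to_repeats <- function(records, instances) {
  if (nrow(records) == 0L || nrow(instances) == 0L) {
    return(cbind(records[0, , drop = FALSE],
                 data.frame(repeat_name = character(0))))
  }
  gr_c <- .as_granges(records$chrom, records$pos, records$pos + 1L)
  gr_i <- .as_granges(instances$chrom, instances$start, instances$end)
  ov <- GenomicRanges::findOverlaps(gr_c, gr_i)
  out <- records[S4Vectors::queryHits(ov), , drop = FALSE]
  out$repeat_name <- instances$repeat_name[S4Vectors::subjectHits(ov)]
  rownames(out) <- NULL
  out
}

#' Per-repeat, per-cell methylation percentage
#'
#' Read-weighted aggregation by default: the percentage for a (repeat type,
#' cell) pair is `100 * sum(meth_reads) / sum(total_reads)` over the repeat's
#' assigned, coverage-filtered CpGs in that cell. A `cpg_mean` mode (the
#' unweighted mean of per-CpG percentages) is provided for comparison. Pairs
#' with no surviving CpG are absent from the output (missing, never 0).
#'
#' @param assigned output of [assign_cpgs_to_repeats()] on coverage-filtered
#'   records.
#' @param mode `"read_weighted"` (default) or `"cpg_mean"`.
#' @return data.frame `repeat_name`, `cell_id`, `percent`, `n_cpgs`,
#'   `total_reads_used`.
#' @export
repeat_methylation_percent <- function(assigned,
                                       mode = c("read_weighted", "cpg_mean")) {
  mode <- match.arg(mode)
  if (nrow(assigned) == 0L)
    return(data.frame(repeat_name = character(0), cell_id = character(0),
                      percent = numeric(0), n_cpgs = integer(0),
                      total_reads_used = integer(0)))
  key <- interaction(assigned$repeat_name, assigned$cell_id, drop = TRUE)
  meth <- tapply(assigned$meth_reads, key, sum)
  total <- tapply(assigned$total_reads, key, sum)
  n <- tapply(assigned$meth_reads, key, length)
  pct_cpg <- tapply(100 * assigned$meth_reads / assigned$total_reads, key, mean)
  first <- !duplicated(key)
  ord <- match(levels(key), key[first])
  out <- data.frame(
    repeat_name = assigned$repeat_name[first][ord],
    cell_id = assigned$cell_id[first][ord],
    percent = if (mode == "read_weighted") as.numeric(100 * meth / total)
              else as.numeric(pct_cpg),
    n_cpgs = as.integer(n),
    total_reads_used = as.integer(total),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  .assert(all(out$percent >= 0 & out$percent <= 100),
          "methylation percentage outside [0, 100]")
  out
}

#' Per-stage methylation summaries
#'
#' Groups per-cell per-repeat methylation percentages by developmental stage
#' and either repeat class or repeat type, returning the pooled values with
#' their mean and standard error of the mean (the table behind per-stage box
#' plots and class-level trend lines).
#'
#' @param meth output of [repeat_methylation_percent()].
#' @param meta cell metadata.
#' @param classes named character vector repeat name -> class; required when
#'   `grouping = "class"`.
#' @param grouping `"class"` (default) or `"repeat"`.
#' @return list with `values` (long data.frame `group`, `stage`, `percent`)
#'   and `summary` (`group`, `stage`, `mean`, `sem`, `n`).
#' @export
stage_methylation_summary <- function(meth, meta, classes = NULL,
                                      grouping = c("class", "repeat")) {
  grouping <- match.arg(grouping)
  if (grouping == "class") {
    .assert(!is.null(classes) && all(meth$repeat_name %in% names(classes)),
            "class map missing for some repeats")
    grp <- unname(classes[meth$repeat_name])
  } else {
    grp <- meth$repeat_name
  }
  stage <- as.character(meta$stage[match(meth$cell_id, meta$cell_id)])
  .assert(!anyNA(stage), "cell(s) in methylation table missing from metadata")
  values <- data.frame(group = grp, stage = stage, percent = meth$percent,
                       stringsAsFactors = FALSE)
  agg <- split(values$percent,
               interaction(values$group, values$stage, drop = TRUE, sep = "\t"))
  keys <- strsplit(names(agg), "\t", fixed = TRUE)
  summary <- data.frame(
    group = vapply(keys, `[`, "", 1L),
    stage = vapply(keys, `[`, "", 2L),
    mean = vapply(agg, mean, 0),
    sem = vapply(agg, function(v)
      if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    n = lengths(agg), stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(values = values, summary = summary)
}
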