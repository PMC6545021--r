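#' Read a repeat-instance annotation table
#'
#' Parses RepeatMasker-style repeat instances into the package's canonical
#' 0-based half-open representation. Two dialects are supported:
#' \describe{
#'   \item{`bed6+class`}{BED-native: `chrom, start, end, repeat_name,
#'     repeat_class, strand[, repeat_family]`; coordinates already 0-based
#'     half-open.}
#'   \item{`ucsc_rmsk`}{UCSC rmsk-style table: `chrom, start, end,
#'     repeat_name, repeat_class, repeat_family, strand` with 1-based
#'     inclusive starts; start is shifted by one on read so that the
#'     conversion happens exactly once, at the boundary.}
#' }
#' Repeat classes outside [repeat_classes()] are mapped to `"Other"` with a
#' warning rather than an error, since the RepeatMasker class vocabulary
#' drifts between releases.
#'
#' @param path path to a tab-separated annotation file ('#' lines ignored).
#' @param dialect input dialect, see above.
#' @return data.frame with columns `chrom`, `start`, `end`, `repeat_name`,
#'   `repeat_class`, `repeat_family`, `strand` (0-based half-open).
#' @export
read_repeat_annotation <- function(path, dialect = c("bed6+class", "ucsc_rmsk")) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nmin <- if (dialect == "bed6+class") 6L else 7L
  nf <- lengths(fields)
  if (any(nf < nmin))
    .halt("malformed annotation line %d: expected >= %d tab-separated fields, got %d",
          lineno[which(nf < nmin)[1L]], nmin, nf[which(nf < nmin)[1L]])
  m <- do.call(rbind, fields)
  if (dialect == "bed6+class") {
    out <- data.frame(chrom = m[, 1L],
                      start = suppressWarnings(as.integer(m[, 2L])),
                      end = suppressWarnings(as.integer(m[, 3L])),
                      repeat_name = m[, 4L],
                      repeat_class = m[, 5L],
                      repeat_family = if (ncol(m) >= 7L) m[, 7L] else m[, 5L],
                      strand = m[, 6L],
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = m[, 1L],
                      start = suppressWarnings(as.integer(m[, 2L])) - 1L,
                      end = suppressWarnings(as.integer(m[, 3L])),
                      repeat_name = m[, 4L],
                      repeat_class = m[, 5L],
                      repeat_family = m[, 6L],
                      strand = m[, 7L],
                      stringsAsFactors = FALSE)
  }
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0L)
    .halt("malformed annotation line %d: non-numeric coordinates", lineno[bad[1L]])
  validate_repeat_instances(out)
}

#' Validate repeat instances
#'
#' Enforces the `RepeatInstance` invariants: `start < end`, non-empty
#' `repeat_name`, strand in `{+, -, .}`, class in the closed set (unknown
#' classes mapped to `"Other"` with a warning).
#'
#' @param inst data.frame of repeat instances.
#' @return the validated (possibly class-remapped) data.frame.
#' @export
validate_repeat_instances <- function(inst) {
  need <- c("chrom", "start", "end", "repeat_name", "repeat_class",
            "repeat_family", "strand")
  .assert(all(need %in% names(inst)),
          "repeat instances missing column(s): %s",
          paste(setdiff(need, names(inst)), collapse = ", "))
  bad <- which(!(inst$start < inst$end))
  if (length(bad) > 0L)
    .halt("repeat instance %d (%s): start (%d) must be < end (%d)",
          bad[1L], inst$repeat_name[bad[1L]], inst$start[bad[1L]], inst$end[bad[1L]])
  .assert(all(nzchar(inst$repeat_name)), "empty repeat_name in annotation")
  .assert(all(inst$strand %in% c("+", "-", ".")),
          "strand must be one of +, -, .")
  unknown <- !(inst$repeat_class %in% repeat_classes())
  if (any(unknown)) {
    warning(sprintf("%d instance(s) with unknown repeat class (%s) mapped to 'Other'",
                    sum(unknown),
                    paste(unique(inst$repeat_class[unknown]), collapse = ", ")),
            call. = FALSE)
    inst$repeat_class[unknown] <- "Other"
  }
  inst
}

#' Write repeat instances as BED6+class
#'
#' Inverse of [read_repeat_annotation()] for the `bed6+class` dialect
#' (with the family as a seventh column); the pair is a lossless round trip.
#'
#' @param inst validated repeat instance data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_annotation <- function(inst, path) {
  inst <- validate_repeat_instances(inst)
  out <- inst[, c("chrom", "start", "end", "repeat_name", "repeat_class",
                  "strand", "repeat_family")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-CpG methylation records
#'
#' Canonical columns are read counts: `chrom, pos, meth_reads, total_reads,
#' cell_id` (0-based positions, tab-separated, no header, '#' lines ignored).
#' A percent+coverage dialect (`chrom, pos, percent, coverage, cell_id`) is
#' accepted and converted with round-half-up:
#' `meth_reads = floor(percent * coverage / 100 + 0.5)`; the conversion is
#' reported via `message()` so it is visible in the run log.
#'
#' @param path input path.
#' @param dialect `"counts"` (default) or `"percent"`.
#' @return data.frame with columns `cell_id`, `chrom`, `pos`, `meth_reads`,
#'   `total_reads`.
#' @export
read_cpg_records <- function(path, dialect = c("counts", "percent")) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "v3", "v4", "cell_id"))
  if (dialect == "percent") {
    message(sprintf(
      "read_cpg_records: converting percent+coverage dialect to read counts (round-half-up) for %d records",
      nrow(df)))
    total <- as.integer(df$v4)
    meth <- as.integer(floor(df$v3 * total / 100 + 0.5))
  } else {
    meth <- as.integer(df$v3)
    total <- as.integer(df$v4)
  }
  out <- data.frame(cell_id = df$cell_id, chrom = df$chrom,
                    pos = as.integer(df$pos),
                    meth_reads = meth, total_reads = total,
                    stringsAsFactors = FALSE)
  validate_cpg_records(out)
}

#' Validate per-CpG records
#'
#' Enforces `0 <= meth_reads <= total_reads` and non-negative positions.
#'
#' @param rec data.frame of CpG records.
#' @return `rec`, validated.
#' @export
validate_cpg_records <- function(rec) {
  need <- c("cell_id", "chrom", "pos", "meth_reads", "total_reads")
  .assert(all(need %in% names(rec)),
          "CpG records missing column(s): %s",
          paste(setdiff(need, names(rec)), collapse = ", "))
  bad <- which(rec$meth_reads > rec$total_reads)
  if (length(bad) > 0L)
    .halt("CpG record %d (%s:%d, cell %s): meth_reads (%d) exceeds total_reads (%d)",
          bad[1L], rec$chrom[bad[1L]], rec$pos[bad[1L]], rec$cell_id[bad[1L]],
          rec$meth_reads[bad[1L]], rec$total_reads[bad[1L]])
  .assert(all(rec$meth_reads >= 0L) && all(rec$total_reads >= 0L),
          "negative read counts in CpG records")
  .assert(all(rec$pos >= 0L), "negative CpG position")
  rec
}

#' Write per-CpG records in the canonical counts dialect
#'
#' @param rec validated CpG record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_records <- function(rec, path) {
  rec <- validate_cpg_records(rec)
  out <- rec[, c("chrom", "pos", "meth_reads", "total_reads", "cell_id")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature-by-cell count matrix
#'
#' TSV with a header of cell ids and the first column holding feature
#' (repeat or gene) labels. Fractional values are accepted: upstream repeat
#' quantifiers distribute multi-mapping reads fractionally across repeat
#' types.
#'
#' @param path input path.
#' @return numeric matrix, features in rows, cells in columns.
#' @export
read_count_matrix <- function(path) {
  df <- .read_tsv(path)
  labs <- as.character(df[[1L]])
  dup <- labs[duplicated(labs)]
  if (length(dup) > 0L)
    .halt("duplicate row label(s) in count matrix: %s",
          paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labs
  dupc <- colnames(m)[duplicated(colnames(m))]
  if (length(dupc) > 0L)
    .halt("duplicate cell id(s) in count matrix: %s",
          paste(unique(dupc), collapse = ", "))
  .assert(!anyNA(m), "non-numeric or missing values in count matrix")
  if (any(m < 0)) .halt("negative count in matrix (feature %s)",
                        rownames(m)[which(rowSums(m < 0) > 0)[1L]])
  m
}

#' Write a feature-by-cell matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param row_label header for the feature-label column.
#' @param seed,note provenance recorded as header comments
#'   (see [write_result_tsv()]).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, row_label = "feature",
                               seed = NULL, note = NULL) {
  write_result_tsv(as.data.frame(m, check.names = FALSE), path,
                   seed = seed, note = note, row_label = row_label)
}

#' Read cell metadata
#'
#' TSV with header containing at least `cell_id`, `stage`, `embryo_id`.
#' Stages are validated against the fixed developmental order
#' ([repdyn_stages()]) and returned as an ordered factor.
#'
#' @param path input path.
#' @return data.frame with `cell_id`, `stage` (ordered factor), `embryo_id`.
#' @export
read_cell_metadata <- function(path) {
  df <- .read_tsv(path)
  need <- c("cell_id", "stage", "embryo_id")
  .assert(all(need %in% names(df)),
          "cell metadata missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  .assert(!anyDuplicated(df$cell_id), "duplicate cell_id in metadata")
  df$stage <- .as_stage(df$stage)
  df[, need]
}

#' Write cell metadata
#'
#' @param meta data.frame with `cell_id`, `stage`, `embryo_id`.
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_cell_metadata <- function(meta, path, seed = NULL) {
  out <- data.frame(cell_id = meta$cell_id, stage = as.character(meta$stage),
                    embryo_id = meta$embryo_id, stringsAsFactors = FALSE)
  write_result_tsv(out, path, seed = seed)
}

#' Read gene models with TSS and strand
#'
#' Two formats are supported:
#' \describe{
#'   \item{`bed6`}{`chrom, start, end, gene_id, score, strand`, 0-based
#'     half-open; the TSS is `start` on the + strand and `end - 1` on the
#'     - strand.}
#'   \item{`gtf`}{minimal GTF with `gene` and/or `transcript` features and a
#'     `gene_id` (and optionally `transcript_id`) attribute; 1-based closed
#'     coordinates converted once at the boundary.}
#' }
#' For GTF input, `tss_per` chooses whether one TSS is taken per gene
#' (`feature == "gene"`) or per transcript (`feature == "transcript"`, keyed
#' by `transcript_id` when present); the choice is recorded in the returned
#' object's `"tss_per"` attribute.
#'
#' @param path input path.
#' @param format `"bed6"` or `"gtf"`.
#' @param tss_per `"gene"` or `"transcript"` (GTF only).
#' @return data.frame with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_gene_models <- function(path, format = c("bed6", "gtf"),
                             tss_per = c("gene", "transcript")) {
  format <- match.arg(format)
  tss_per <- match.arg(tss_per)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "bed6") {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "gene_id",
                                          "score", "strand"))
    out <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                      tss = ifelse(df$strand == "+", df$start, df$end - 1L),
                      strand = df$strand, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             quote = "", stringsAsFactors = FALSE)
    .assert(ncol(raw) >= 9L, "GTF requires 9 tab-separated columns")
    raw <- raw[raw[[3L]] == tss_per, , drop = FALSE]
    .assert(nrow(raw) > 0L, "no '%s' features found in GTF", tss_per)
    grab <- function(attr, key) {
      m <- regmatches(attr, regexec(sprintf('%s "([^"]+)"', key), attr))
      vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
    }
    ids <- grab(raw[[9L]], if (tss_per == "transcript") "transcript_id" else "gene_id")
    if (anyNA(ids) && tss_per == "transcript") ids <- grab(raw[[9L]], "gene_id")
    .assert(!anyNA(ids), "GTF attribute column lacks gene_id/transcript_id")
    # GTF is 1-based closed: 0-based TSS is start-1 (+) or end-1 (-)
    out <- data.frame(gene_id = ids, chrom = raw[[1L]],
                      tss = ifelse(raw[[7L]] == "+",
                                   as.integer(raw[[4L]]) - 1L,
                                   as.integer(raw[[5L]]) - 1L),
                      strand = raw[[7L]], stringsAsFactors = FALSE)
  }
  .assert(all(out$strand %in% c("+", "-")), "gene strand must be + or -")
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0L)
    .halt("duplicate gene id(s) in annotation: %s",
          paste(unique(dup)[seq_len(min(5, length(unique(dup))))], collapse = ", "))
  .assert(all(out$tss >= 0L), "negative TSS coordinate")
  attr(out, "tss_per") <- tss_per
  out
}

#' Write gene models as BED6
#'
#' Emits one single-base interval at the TSS per gene; round-trips with
#' [read_gene_models()] in `bed6` format.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom,
                    start = genes$tss,
                    end = genes$tss + 1L,
                    gene_id = genes$gene_id, score = 0L, strand = genes$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view of repeat instances / windows (internal; intervals stay
# half-open at the package surface, IRanges closed form used only here)
.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}
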