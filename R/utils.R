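#' Developmental stage order
#'
#' The fixed developmental ordering used throughout the package: oocyte to
#' late blastocyst, followed by passage-0 and passage-10 embryonic stem cells.
#'
#' @return Character vector of stage labels in developmental order.
#' @export
repdyn_stages <- function() {
  c("oocyte", "zygote", "2cell", "4cell", "8cell", "morula",
    "late_blastocyst", "ESC_P0", "ESC_P10")
}

#' Recognised repeat classes
#'
#' The closed set of repeat classes; annotation readers map anything outside
#' this set to "Other" with a warning.
#'
#' @return Character vector of class labels.
#' @export
repeat_classes <- function() {
  c("LINE", "SINE", "LTR", "DNA", "SVA", "Satellite", "smallRNA", "Other")
}

# stop() with a consistent prefix; keeps condition call out of the message
.halt <- function(...) stop(sprintf(...), call. = FALSE)

.assert <- function(cond, ...) if (!isTRUE(cond)) .halt(...)

# coerce stage column to the fixed ordered factor, failing on unknown labels
.as_stage <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), repdyn_stages())
  if (length(bad) > 0L)
    .halt("unknown developmental stage label(s): %s", paste(bad, collapse = ", "))
  factor(x, levels = repdyn_stages(), ordered = TRUE)
}

# split cell ids by stage, dropping unused stage levels
.cells_by_stage <- function(meta) {
  split(meta$cell_id, droplevels(meta$stage))
}

# sample standard deviation that returns 0 for length-1 input
.sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

#' Write a TSV result table with a provenance header comment
#'
#' All tabular outputs of the pipeline go through this writer, which prefixes
#' the file with comment lines recording the package version and, when given,
#' the seed and a free-text note (e.g. parameter choices). Readers in this
#' package skip '#' comment lines.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed optional integer seed to record.
#' @param note optional one-line note to record.
#' @param row_label if non-NULL, row names are written as a first column with
#'   this header (used for matrices).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, seed = NULL, note = NULL, row_label = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# repdyn %s",
                     as.character(utils::packageVersion("repdyn"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(note)) writeLines(paste0("# ", note), con)
  if (!is.null(row_label)) {
    df <- data.frame(setNames(list(rownames(df)), row_label),
                     as.data.frame(df), check.names = FALSE)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# read a TSV written by write_result_tsv (or any headered TSV); '#' lines skipped
.read_tsv <- function(path, ...) {
  .assert(file.exists(path), "file not found: %s", path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
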