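## TSV readers/writers shared across stages. All tabular outputs carry a
## single header line after an optional '#' metadata block.

# read.delim with required-column validation and '#' comment support;
# errors name the file and the first offending element.
readTsv <- function(file, required = character()) {
  if (!file.exists(file)) abort("input file not found: ", file)
  df <- tryCatch(
    utils::read.delim(file, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) abort("cannot parse '", file, "': ",
                              conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort("'", file, "' is missing column(s): ",
          paste(missing, collapse = ", "))
  df
}

#' Read a CNV call table
#'
#' Native dialect: TSV with header
#' `sample_id chrom start end copy_state [cytoband] [aneuploidy]`, 1-based
#' printed coordinates. With `bed = TRUE` a headerless 4+-column BED file
#' (`chrom start end sample_id[:copy_state]`, 0-based half-open) is
#' converted on read; a missing copy state defaults to deletion with a
#' warning.
#'
#' @param file path to the table.
#' @param bed interpret as 0-based BED (default `FALSE`).
#' @return a [CnvCalls-class] object.
#' @export
readCnvCalls <- function(file, bed = FALSE) {
  if (bed) {
    df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(df) < 4L) abort("BED input needs at least 4 columns")
    name <- strsplit(as.character(df[[4L]]), ":", fixed = TRUE)
    state <- vapply(name, function(x)
      if (length(x) > 1L) x[2L] else NA_character_, character(1L))
    if (anyNA(state)) {
      warning("BED name column lacks a copy state; defaulting to deletion")
      state[is.na(state)] <- "del"
    }
    return(CnvCalls(vapply(name, `[[`, character(1L), 1L),
                    df[[1L]], df[[2L]] + 1L, df[[3L]], state))
  }
  df <- readTsv(file, c("sample_id", "chrom", "start", "end", "copy_state"))
  calls <- CnvCalls(df$sample_id, df$chrom, df$start, df$end, df$copy_state,
                    cytoband = df$cytoband %||% NA_character_,
                    aneuploidy = df$aneuploidy %||% FALSE)
  if (!is.null(df$mvp_score))
    GenomicRanges::mcols(calls)$mvpScore <- as.numeric(df$mvp_score)
  calls
}

#' Write a TSV with a metadata comment block
#'
#' @param df data.frame to write.
#' @param file output path.
#' @param meta optional named character vector written as `# key: value`
#'   lines before the header.
#' @return `file`, invisibly.
#' @export
writeTsv <- function(df, file, meta = NULL) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# CnvCalls (possibly annotated) -> flat data.frame for writing
cnvCallsToDf <- function(calls) {
  mc <- as.data.frame(GenomicRanges::mcols(calls))
  base <- data.frame(
    sample_id = sampleId(calls),
    chrom = as.character(GenomicRanges::seqnames(calls)),
    start = GenomicRanges::start(calls),
    end = GenomicRanges::end(calls),
    copy_state = copyState(calls),
    size_mb = lengthMb(calls),
    region = formatRegion(calls),
    stringsAsFactors = FALSE)
  extra <- mc[, setdiff(colnames(mc), c("sampleId", "copyState")),
              drop = FALSE]
  if (ncol(extra)) cbind(base, extra) else base
}
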