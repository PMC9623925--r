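## Stage 3: map P/LP CNVs to contained protein-coding genes.

#' Normalize gene symbols
#'
#' Uppercase and strip whitespace. No alias resolution is attempted: symbols
#' differing only by an alias count as distinct genes (documented
#' limitation).
#'
#' @param x character vector of symbols.
#' @return normalized character vector.
#' @export
normalizeSymbols <- function(x) toupper(trimws(as.character(x)))

#' Read a gene model
#'
#' Two dialects: a BED-like file (`chrom start end name [score strand]`,
#' 0-based half-open, converted to 1-based on read) when `bed = TRUE`, or a
#' refFlat-like TSV with header `chrom start end symbol biotype`. A missing
#' biotype column defaults every gene to `protein_coding` with a warning.
#'
#' @param file path to the file.
#' @param bed interpret as headerless 0-based BED (default `FALSE`).
#' @return `GRanges` with metadata columns `symbol`, `biotype`.
#' @export
readGeneModel <- function(file, bed = FALSE) {
  if (bed) {
    df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) abort("BED gene model needs at least 4 columns")
    names(df)[1:4] <- c("chrom", "start", "end", "symbol")
    df$start <- df$start + 1L  # 0-based half-open -> 1-based
    df$biotype <- "protein_coding"
  } else {
    df <- readTsv(file, c("chrom", "start", "end", "symbol"))
    if (is.null(df$biotype)) {
      warning("gene model has no 'biotype' column; assuming protein_coding")
      df$biotype <- "protein_coding"
    }
  }
  gr <- newInterval(df$chrom, df$start, df$end)
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    symbol = normalizeSymbols(df$symbol),
    biotype = ifelse(tolower(df$biotype) == "protein_coding",
                     "protein_coding", "other"))
  gr
}

#' Protein-coding genes in a CNV
#'
#' Returns the protein-coding gene symbols whose interval overlaps the CNV.
#' The default `any_overlap` mode counts boundary genes (a partially deleted
#' or duplicated gene is still dosage-affected); `contained` mode restricts
#' to genes lying entirely inside the CNV, for sensitivity analyses. Output
#' is sorted by gene start position and deduplicated by symbol.
#'
#' @param cnv a single-interval `GRanges` / [CnvCalls-class] row.
#' @param geneModel `GRanges` from [readGeneModel()].
#' @param mode `"any_overlap"` (default) or `"contained"`.
#' @return character vector of gene symbols.
#' @export
genesInCnv <- function(cnv, geneModel, mode = c("any_overlap", "contained")) {
  mode <- match.arg(mode)
  if (length(cnv) != 1L) abort("'cnv' must be a single interval")
  .genesPerCnv(cnv, geneModel, mode)[[1L]]
}

# vectorized per-CNV gene lookup on plain coordinate vectors (shared by
# classifyCnvs and cohortGeneUniverse to keep S4 subsetting out of loops)
.genesPerCnv <- function(cnvs, geneModel, mode = "any_overlap") {
  gChrom <- as.character(GenomicRanges::seqnames(geneModel))
  gStart <- GenomicRanges::start(geneModel)
  gEnd <- GenomicRanges::end(geneModel)
  coding <- GenomicRanges::mcols(geneModel)$biotype == "protein_coding"
  sym <- GenomicRanges::mcols(geneModel)$symbol
  cChrom <- as.character(GenomicRanges::seqnames(cnvs))
  cStart <- GenomicRanges::start(cnvs)
  cEnd <- GenomicRanges::end(cnvs)
  lapply(seq_along(cnvs), function(i) {
    hit <- if (mode == "any_overlap") {
      gChrom == cChrom[i] &
        (pmin(gEnd, cEnd[i]) - pmax(gStart, cStart[i]) > 0)
    } else {
      gChrom == cChrom[i] & gStart >= cStart[i] & gEnd <= cEnd[i]
    }
    hit <- hit & coding
    unique(sym[hit][order(gStart[hit])])
  })
}

#' Candidate-gene universe of a CNV set
#'
#' Maps every CNV to its genes and unions the results: a gene inside two
#' CNVs appears under both in `perCnv` but once in `universe`.
#'
#' @param cnvs `GRanges` / [CnvCalls-class] of (typically P/LP) CNVs.
#' @param geneModel `GRanges` from [readGeneModel()].
#' @param mode passed to [genesInCnv()].
#' @return list with `universe` (sorted unique symbols) and `perCnv`
#'   (list of per-CNV symbol vectors, named by region string).
#' @export
cohortGeneUniverse <- function(cnvs, geneModel,
                               mode = c("any_overlap", "contained")) {
  mode <- match.arg(mode)
  perCnv <- .genesPerCnv(cnvs, geneModel, mode)
  names(perCnv) <- if (length(cnvs)) formatRegion(cnvs) else character()
  list(universe = sort(unique(unlist(perCnv))), perCnv = perCnv)
}
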