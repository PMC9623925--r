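## Stage 2: per-CNV verdicts from three independent sources and the
## any-of-three pathogenic / likely pathogenic (P/LP) consensus.

#' Pathogenicity categories
#'
#' The five interpretation tiers plus `not_mentioned` for CNVs a source does
#' not cover. Severity (for tie-breaking only) is
#' pathogenic > likely_pathogenic > uncertain > likely_benign > benign;
#' `not_mentioned` is outside the order and never contributes to consensus.
#'
#' @return character vector of category levels, most severe first.
#' @export
pathogenicityLevels <- function() {
  c("pathogenic", "likely_pathogenic", "uncertain", "likely_benign",
    "benign", "not_mentioned")
}

#' Normalize category labels
#'
#' Accepts display spellings ("Likely pathogenic", "NM", "not mentioned")
#' and returns a factor over [pathogenicityLevels()].
#'
#' @param x character vector of category labels.
#' @return factor over the canonical levels.
#' @export
asCategory <- function(x) {
  key <- gsub("[ -]", "_", tolower(trimws(as.character(x))))
  key[key %in% c("nm", "not_mentioned", "")] <- "not_mentioned"
  bad <- !(key %in% pathogenicityLevels())
  if (any(bad))
    abort("unknown pathogenicity category: ",
          paste(unique(x[bad]), collapse = ", "))
  factor(key, levels = pathogenicityLevels())
}

.isPlp <- function(cat) as.character(cat) %in%
  c("pathogenic", "likely_pathogenic")

#' Bin MVP scores into pathogenicity categories
#'
#' The meta-voting prediction (MVP) score in `[0, 1]` is binned by four
#' ascending cut-points into benign < likely_benign < uncertain <
#' likely_pathogenic < pathogenic, each bin closed on the left
#' (`score >= cutpoint` enters the next tier). The default cut-points
#' `c(0.14, 0.18, 0.50, 0.75)` are a calibration consistent with every
#' published (score, label) pair this package's fixture carries; they are not
#' an authoritative constant of the upstream predictor and can be overridden.
#'
#' @param score numeric vector of MVP scores in `[0, 1]`.
#' @param cutpoints four strictly ascending cut-points in (0, 1).
#' @return factor of categories.
#' @examples
#' mvpCategory(c(0.862, 0.527, 0.187, 0.123))
#' @export
mvpCategory <- function(score, cutpoints = c(0.14, 0.18, 0.50, 0.75)) {
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0) ||
      any(cutpoints <= 0) || any(cutpoints >= 1))
    abort("'cutpoints' must be 4 strictly ascending values in (0, 1)")
  score <- as.numeric(score)
  if (anyNA(score) || any(score < 0 | score > 1))
    abort("MVP scores must lie in [0, 1]")
  tiers <- c("benign", "likely_benign", "uncertain", "likely_pathogenic",
             "pathogenic")
  factor(tiers[findInterval(score, cutpoints) + 1L],
         levels = pathogenicityLevels())
}

#' Read a DECIPHER-style region-verdict table
#'
#' TSV dialect `chrom start end category` (header required).
#'
#' @param file path to a TSV file.
#' @return `GRanges` with a `category` metadata column.
#' @export
readDecipherRegions <- function(file) {
  df <- readTsv(file, c("chrom", "start", "end", "category"))
  gr <- newInterval(df$chrom, df$start, df$end)
  GenomicRanges::mcols(gr)$category <- asCategory(df$category)
  gr
}

#' Verdict from curated region overlap
#'
#' Each call inherits the category of its best-overlapping curated region:
#' among regions whose reciprocal overlap strictly exceeds `minReciprocal`,
#' the one with the highest overlap wins, ties broken toward the more severe
#' category. Calls matching no region are `not_mentioned`.
#'
#' @param calls `GRanges` / [CnvCalls-class] of query CNVs.
#' @param regions `GRanges` with a `category` column
#'   (see [readDecipherRegions()]).
#' @param minReciprocal strict reciprocal-overlap threshold (default 0.5).
#' @return factor of categories, one per call.
#' @export
decipherVerdict <- function(calls, regions, minReciprocal = 0.5) {
  assertScalarNumber(minReciprocal, "minReciprocal", 0, 1)
  cat <- asCategory(GenomicRanges::mcols(regions)$category)
  rChrom <- as.character(GenomicRanges::seqnames(regions))
  rStart <- GenomicRanges::start(regions)
  rEnd <- GenomicRanges::end(regions)
  qChrom <- as.character(GenomicRanges::seqnames(calls))
  qStart <- GenomicRanges::start(calls)
  qEnd <- GenomicRanges::end(calls)
  out <- rep("not_mentioned", length(calls))
  for (i in seq_along(calls)) {
    ro <- .ro1(qChrom[i], qStart[i], qEnd[i], rChrom, rStart, rEnd)
    keep <- which(ro > minReciprocal)
    if (!length(keep)) next
    # highest overlap first, then severity rank (level order = severity)
    keep <- keep[order(-ro[keep], as.integer(cat[keep]))]
    out[i] <- as.character(cat[keep[1L]])
  }
  factor(out, levels = pathogenicityLevels())
}

#' Read an OMIM-style gene-to-association map
#'
#' TSV dialect `gene_symbol association` with `association` in
#' `disease` / `phenotype`. Symbols are uppercased.
#'
#' @param file path to a TSV file.
#' @return data.frame with columns `gene`, `association`.
#' @export
readOmimMap <- function(file) {
  df <- readTsv(file, c("gene_symbol", "association"))
  assoc <- tolower(trimws(df$association))
  if (!all(assoc %in% c("disease", "phenotype")))
    abort("'association' must be 'disease' or 'phenotype'")
  data.frame(gene = normalizeSymbols(df$gene_symbol), association = assoc,
             stringsAsFactors = FALSE)
}

#' Verdict from gene disease associations
#'
#' A CNV is `pathogenic` when it contains at least one gene associated with a
#' disease, `likely_pathogenic` when it contains only genes associated with
#' phenotypic alterations, and `not_mentioned` otherwise.
#'
#' @param genes character vector of gene symbols in the CNV (one CNV), or a
#'   list of such vectors (one per CNV).
#' @param geneMap data.frame from [readOmimMap()].
#' @return factor of categories.
#' @export
omimVerdict <- function(genes, geneMap) {
  if (!is.list(genes)) genes <- list(genes)
  disease <- geneMap$gene[geneMap$association == "disease"]
  pheno <- geneMap$gene[geneMap$association == "phenotype"]
  out <- vapply(genes, function(g) {
    g <- normalizeSymbols(g)
    if (any(g %in% disease)) "pathogenic"
    else if (any(g %in% pheno)) "likely_pathogenic"
    else "not_mentioned"
  }, character(1L))
  factor(out, levels = pathogenicityLevels())
}

#' Any-of-three P/LP consensus
#'
#' A CNV is called pathogenic/likely pathogenic when any of the three verdict
#' sources classifies it as `pathogenic` or `likely_pathogenic`; `uncertain`,
#' `likely_benign`, `benign` and `not_mentioned` never contribute.
#'
#' @param mvp,decipher,omim category vectors (coerced via [asCategory()]).
#' @return logical vector, `TRUE` for consensus P/LP.
#' @examples
#' consensusClassify("benign", "not_mentioned", "pathogenic") # TRUE
#' @export
consensusClassify <- function(mvp, decipher, omim) {
  .isPlp(asCategory(mvp)) | .isPlp(asCategory(decipher)) |
    .isPlp(asCategory(omim))
}

#' Annotate candidate CNVs with three verdicts and the consensus
#'
#' Convenience wrapper assembling the full stage-2 annotation. Verdicts can
#' be supplied directly (e.g. from a published table) or computed from their
#' sources: MVP categories from `mvpScore` via [mvpCategory()], region
#' verdicts from `decipherRegions` via [decipherVerdict()], and gene-evidence
#' verdicts from `geneModel` + `omimMap` via [genesInCnv()] and
#' [omimVerdict()].
#'
#' @param calls a [CnvCalls-class] object.
#' @param mvpScore numeric scores (optional if `mvpCat` given).
#' @param mvpCat,decipherCat,omimCat precomputed category vectors.
#' @param decipherRegions `GRanges` of curated regions.
#' @param omimMap data.frame from [readOmimMap()].
#' @param geneModel `GRanges` gene model (see [readGeneModel()]).
#' @param cutpoints passed to [mvpCategory()].
#' @param minReciprocal passed to [decipherVerdict()].
#' @return `calls` with metadata columns `mvpScore`, `mvpCategory`,
#'   `decipherCategory`, `omimCategory`, `consensusPlp`.
#' @export
classifyCnvs <- function(calls, mvpScore = NULL, mvpCat = NULL,
                         decipherCat = NULL, omimCat = NULL,
                         decipherRegions = NULL, omimMap = NULL,
                         geneModel = NULL,
                         cutpoints = c(0.14, 0.18, 0.50, 0.75),
                         minReciprocal = 0.5) {
  n <- length(calls)
  if (is.null(mvpCat))
    mvpCat <- if (is.null(mvpScore)) rep("not_mentioned", n)
    else mvpCategory(mvpScore, cutpoints)
  if (is.null(decipherCat))
    decipherCat <- if (is.null(decipherRegions)) rep("not_mentioned", n)
    else decipherVerdict(calls, decipherRegions, minReciprocal)
  if (is.null(omimCat))
    omimCat <- if (is.null(omimMap) || is.null(geneModel))
      rep("not_mentioned", n)
    else omimVerdict(.genesPerCnv(calls, geneModel), omimMap)
  mc <- GenomicRanges::mcols(calls)
  mc$mvpScore <- if (is.null(mvpScore)) rep(NA_real_, n)
  else as.numeric(mvpScore)
  mc$mvpCategory <- asCategory(mvpCat)
  mc$decipherCategory <- asCategory(decipherCat)
  mc$omimCategory <- asCategory(omimCat)
  mc$consensusPlp <- consensusClassify(mc$mvpCategory, mc$decipherCategory,
                                       mc$omimCategory)
  GenomicRanges::mcols(calls) <- mc
  calls
}
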