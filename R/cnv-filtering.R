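## Stage 1: exclude aneuploidies / gross chromosomal aberrations at the
## patient level, then drop CNVs common in the general population by
## reciprocal-overlap matching against a DGV-style database.

#' Flag patients with aneuploidies or gross chromosomal aberrations
#'
#' A patient is flagged `gross_aberration` when at least one call exceeds the
#' size threshold (strictly more than `sizeThresholdMb` megabases of
#' `end - start` length), and `aneuploidy` when at least one call carries the
#' aneuploidy flag or, when chromosome lengths are supplied, spans at least
#' `aneuploidySpanFraction` of its chromosome. Aneuploidy takes precedence
#' when both apply. Flagged patients are excluded wholesale downstream: all
#' of their calls drop and they leave the diagnostic-yield denominator.
#'
#' @param calls a [CnvCalls-class] object.
#' @param sizeThresholdMb gross-aberration size threshold in Mb (default 30).
#' @param chromLengths optional named numeric vector of chromosome lengths
#'   (names over `1..22, X, Y`) enabling the span-based aneuploidy check.
#' @param aneuploidySpanFraction fraction of a chromosome a call must span to
#'   count as an aneuploidy (default 0.9).
#' @return data.frame with columns `sampleId`, `reason`, one row per flagged
#'   patient.
#' @examples
#' calls <- CnvCalls(c("p1", "p2"), c("3", "5"),
#'                   c(1e6, 1e6), c(35.8e6, 3.5e6), c("dup", "del"))
#' flagGross(calls) # p1 flagged, p2 not
#' @export
flagGross <- function(calls, sizeThresholdMb = 30, chromLengths = NULL,
                      aneuploidySpanFraction = 0.9) {
  assertScalarNumber(sizeThresholdMb, "sizeThresholdMb", lo = 1e-9)
  if (length(calls) == 0L)
    return(data.frame(sampleId = character(), reason = character(),
                      stringsAsFactors = FALSE))
  aneu <- aneuploidyFlag(calls)
  if (!is.null(chromLengths)) {
    cl <- chromLengths[as.character(GenomicRanges::seqnames(calls))]
    aneu <- aneu | (!is.na(cl) & lengthBp(calls) >= aneuploidySpanFraction * cl)
  }
  gross <- lengthBp(calls) > sizeThresholdMb * 1e6
  sid <- sampleId(calls)
  aneuPat <- unique(sid[aneu])
  grossPat <- setdiff(unique(sid[gross]), aneuPat)
  out <- data.frame(
    sampleId = c(aneuPat, grossPat),
    reason = c(rep("aneuploidy", length(aneuPat)),
               rep("gross_aberration", length(grossPat))),
    stringsAsFactors = FALSE)
  out[order(out$sampleId), , drop = FALSE]
}

#' Read a DGV-style population CNV table
#'
#' Expects the export dialect `variantaccession chr start end varianttype`
#' (header required, extra columns ignored); `varianttype` values
#' gain/loss/gain+loss map onto duplication/deletion/both.
#'
#' @param file path to a TSV file.
#' @return `GRanges` with metadata columns `accession` and `copyState`
#'   (`deletion`, `duplication` or `both`).
#' @export
readPopulationCnvs <- function(file) {
  df <- readTsv(file, c("variantaccession", "chr", "start", "end",
                        "varianttype"))
  gr <- newInterval(df$chr, df$start, df$end)
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    accession = as.character(df$variantaccession),
    copyState = normalizeCopyState(df$varianttype, allowBoth = TRUE))
  gr
}

#' Test CNVs against a population database
#'
#' A call is *common* when strictly more than `maxOccurrences` population
#' records match it at strictly more than `minReciprocal` reciprocal overlap
#' ("more than four occurrences ... overlapping more than 50%"): exactly four
#' matches leave a call rare. By default a matching record must share the
#' call's copy state; database records typed `both` match either state.
#'
#' @param calls a [CnvCalls-class] object (or plain `GRanges` with a
#'   `copyState` column when `matchCopyState = TRUE`).
#' @param popdb population records from [readPopulationCnvs()] or
#'   [simulatePopdb()].
#' @param minReciprocal reciprocal-overlap threshold, strict (default 0.5).
#' @param maxOccurrences occurrence threshold, strict (default 4).
#' @param matchCopyState require matching copy state (default `TRUE`).
#' @return data.frame with columns `common` (logical) and `nMatches`
#'   (integer), one row per call.
#' @export
isCommon <- function(calls, popdb, minReciprocal = 0.5, maxOccurrences = 4,
                     matchCopyState = TRUE) {
  assertScalarNumber(minReciprocal, "minReciprocal", 0, 1)
  assertScalarNumber(maxOccurrences, "maxOccurrences", 0)
  n <- length(calls)
  if (n == 0L)
    return(data.frame(common = logical(), nMatches = integer()))
  popState <- as.character(GenomicRanges::mcols(popdb)$copyState)
  pChrom <- as.character(GenomicRanges::seqnames(popdb))
  pStart <- GenomicRanges::start(popdb)
  pEnd <- GenomicRanges::end(popdb)
  qChrom <- as.character(GenomicRanges::seqnames(calls))
  qStart <- GenomicRanges::start(calls)
  qEnd <- GenomicRanges::end(calls)
  qState <- copyState(calls)
  nMatches <- integer(n)
  for (i in seq_len(n)) {
    hit <- .ro1(qChrom[i], qStart[i], qEnd[i], pChrom, pStart, pEnd) >
      minReciprocal
    if (matchCopyState && !is.null(popState))
      hit <- hit & (popState == qState[i] | popState == "both")
    nMatches[i] <- sum(hit)
  }
  data.frame(common = nMatches > maxOccurrences, nMatches = nMatches)
}

#' Triage a CNV cohort
#'
#' Applies the two exclusion stages in order: [flagGross()] removes whole
#' patients (all of their calls, whatever their size), then [isCommon()]
#' removes population-polymorphic calls among the survivors. The result
#' partitions the input calls exactly; filtering is idempotent on its own
#' candidate output.
#'
#' @param calls a [CnvCalls-class] object with the cohort's raw calls.
#' @param popdb population CNV records; `NULL` skips the common-CNV stage.
#' @param samples optional character vector with the full patient roster
#'   (patients without calls still count toward the denominator); defaults to
#'   the samples present in `calls`.
#' @param sizeThresholdMb,chromLengths,aneuploidySpanFraction passed to
#'   [flagGross()].
#' @param minReciprocal,maxOccurrences,matchCopyState passed to [isCommon()].
#' @return a [FilterReport-class] object.
#' @examples
#' calls <- CnvCalls(c("a", "b"), c("1", "2"), c(1e6, 1e6),
#'                   c(40e6, 2e6), c("dup", "del"))
#' filterCohort(calls, popdb = NULL, samples = c("a", "b", "c"))
#' @export
filterCohort <- function(calls, popdb = NULL, samples = NULL,
                         sizeThresholdMb = 30, chromLengths = NULL,
                         aneuploidySpanFraction = 0.9,
                         minReciprocal = 0.5, maxOccurrences = 4,
                         matchCopyState = TRUE) {
  samples <- unique(samples %||% sampleId(calls))
  flagged <- flagGross(calls, sizeThresholdMb, chromLengths,
                       aneuploidySpanFraction)
  flagged <- flagged[flagged$sampleId %in% samples, , drop = FALSE]
  inFlagged <- sampleId(calls) %in% flagged$sampleId
  survivors <- calls[!inFlagged]
  common <- if (!is.null(popdb) && length(survivors)) {
    isCommon(survivors, popdb, minReciprocal, maxOccurrences,
             matchCopyState)$common
  } else rep(FALSE, length(survivors))
  excl <- c(calls[inFlagged], survivors[common])
  reason <- c(rep("patient_excluded", sum(inFlagged)),
              rep("common_in_population", sum(common)))
  if (length(excl)) GenomicRanges::mcols(excl)$reason <- reason
  else GenomicRanges::mcols(excl)$reason <- character(0)
  methods::new("FilterReport",
               excludedPatients = flagged,
               excludedCnvs = methods::as(excl, "CnvCalls"),
               candidates = methods::as(survivors[!common], "CnvCalls"),
               nPatients = length(samples),
               denominator = length(samples) - nrow(flagged))
}
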