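#' CnvCalls: per-patient CNV calls
#'
#' A [GenomicRanges::GRanges] subclass holding one row per observed
#' copy-number segment, with required metadata columns `sampleId` (non-empty
#' character) and `copyState` (`"deletion"` or `"duplication"`), plus optional
#' `cytoband` and `aneuploidy` (logical flag for whole-chromosome events).
#' Coordinates follow the printed 1-based convention of [parseRegion()].
#'
#' @slot elementMetadata inherited; carries the columns above.
#' @seealso [CnvCalls()], [readCnvCalls()], [filterCohort()]
#' @exportClass CnvCalls
setClass("CnvCalls", contains = "GRanges")

.copyStates <- c("deletion", "duplication")

setValidity("CnvCalls", function(object) {
  mc <- GenomicRanges::mcols(object)
  msg <- character()
  if (!all(c("sampleId", "copyState") %in% colnames(mc)))
    return("metadata columns 'sampleId' and 'copyState' are required")
  if (length(object)) {
    sid <- as.character(mc$sampleId)
    if (anyNA(sid) || any(!nzchar(sid)))
      msg <- c(msg, "'sampleId' must be non-empty")
    if (!all(as.character(mc$copyState) %in% .copyStates))
      msg <- c(msg, "'copyState' must be 'deletion' or 'duplication'")
    if (any(lengthBp(object) <= 0))
      msg <- c(msg, "intervals must satisfy end > start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CnvCalls object
#'
#' @param sampleId character vector of patient identifiers.
#' @param chrom chromosome labels (any dialect accepted by
#'   [normalizeChrom()]).
#' @param start,end 1-based coordinates with `end > start`.
#' @param copyState `"deletion"`/`"duplication"`; the abbreviations
#'   `del`/`dup`/`loss`/`gain` are accepted and normalized.
#' @param cytoband optional cytoband labels.
#' @param aneuploidy optional logical flags marking whole-chromosome events.
#' @return a [CnvCalls-class] object.
#' @examples
#' CnvCalls("case5", "8", 128538700, 146262124, "dup")
#' @export
CnvCalls <- function(sampleId, chrom, start, end, copyState,
                     cytoband = NA_character_, aneuploidy = FALSE) {
  if (length(sampleId) == 0L) {
    gr <- newInterval(character(), numeric(), numeric())
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
      sampleId = character(), copyState = character(),
      cytoband = character(), aneuploidy = logical())
    return(methods::new("CnvCalls", gr))
  }
  gr <- newInterval(chrom, start, end)
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    sampleId = as.character(sampleId),
    copyState = normalizeCopyState(copyState),
    cytoband = rep_len(as.character(cytoband), length(gr)),
    aneuploidy = rep_len(as.logical(aneuploidy), length(gr)))
  methods::new("CnvCalls", gr)
}

#' @rdname CnvCalls
#' @param x a `CnvCalls` object.
#' @export
sampleId <- function(x) as.character(GenomicRanges::mcols(x)$sampleId)

#' @rdname CnvCalls
#' @export
copyState <- function(x) as.character(GenomicRanges::mcols(x)$copyState)

#' @rdname CnvCalls
#' @export
aneuploidyFlag <- function(x) {
  f <- GenomicRanges::mcols(x)$aneuploidy
  if (is.null(f)) rep(FALSE, length(x)) else (!is.na(f) & f)
}

#' Normalize copy-state labels
#'
#' @param x character vector of copy-state labels in any common dialect.
#' @param allowBoth also accept `"both"`/`"gain+loss"` (population databases
#'   record variants seen in either state).
#' @return character vector over `deletion`/`duplication` (and `both`).
#' @export
normalizeCopyState <- function(x, allowBoth = FALSE) {
  key <- tolower(trimws(as.character(x)))
  map <- c(del = "deletion", deletion = "deletion", loss = "deletion",
           dup = "duplication", duplication = "duplication",
           gain = "duplication")
  if (allowBoth)
    map <- c(map, both = "both", `gain+loss` = "both", `gain/loss` = "both")
  out <- unname(map[key])
  if (anyNA(out))
    abort("unknown copy state: ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' FilterReport: outcome of cohort-level CNV triage
#'
#' Produced by [filterCohort()]. Partitions the input calls into candidates
#' and exclusions, and records the post-exclusion patient denominator used by
#' diagnostic-yield computations.
#'
#' @slot excludedPatients data.frame with columns `sampleId`, `reason`
#'   (`aneuploidy` or `gross_aberration`).
#' @slot excludedCnvs [CnvCalls-class] with a `reason` metadata column
#'   (`patient_excluded` or `common_in_population`).
#' @slot candidates [CnvCalls-class], the surviving rare calls.
#' @slot nPatients integer, cohort size before exclusions.
#' @slot denominator integer, `nPatients - nrow(excludedPatients)`.
#' @exportClass FilterReport
setClass("FilterReport", representation(
  excludedPatients = "data.frame",
  excludedCnvs = "CnvCalls",
  candidates = "CnvCalls",
  nPatients = "integer",
  denominator = "integer"))

setValidity("FilterReport", function(object) {
  msg <- character()
  ep <- object@excludedPatients
  if (!all(c("sampleId", "reason") %in% names(ep)))
    msg <- c(msg, "excludedPatients needs columns 'sampleId' and 'reason'")
  else if (!all(ep$reason %in% c("aneuploidy", "gross_aberration")))
    msg <- c(msg, "invalid patient exclusion reason")
  if (object@denominator != object@nPatients - nrow(ep))
    msg <- c(msg, "denominator must equal nPatients - excluded patients")
  rs <- GenomicRanges::mcols(object@excludedCnvs)$reason
  if (length(object@excludedCnvs) &&
      (is.null(rs) || !all(rs %in% c("patient_excluded",
                                     "common_in_population"))))
    msg <- c(msg, "invalid CNV exclusion reason")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterReport-class candidate (surviving) calls.
#' @param x,object a `FilterReport`.
#' @export
candidateCnvs <- function(x) x@candidates

#' @describeIn FilterReport-class excluded calls with their reasons.
#' @export
excludedCnvs <- function(x) x@excludedCnvs

#' @describeIn FilterReport-class per-patient exclusions.
#' @export
excludedPatients <- function(x) x@excludedPatients

#' @describeIn FilterReport-class patient count after exclusions (the
#'   diagnostic-yield denominator).
#' @export
yieldDenominator <- function(x) x@denominator

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@nPatients, "patients,",
      nrow(object@excludedPatients), "excluded ->", "denominator",
      object@denominator, "\n")
  cat("  candidate CNVs:", length(object@candidates), "\n")
  tab <- table(GenomicRanges::mcols(object@excludedCnvs)$reason)
  if (length(tab))
    cat("  excluded CNVs: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(NULL)
})
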