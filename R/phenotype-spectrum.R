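## Stage 5: syndromic vs isolated CHD spectrum per CNV region, from a
## DECIPHER-style patient table.

#' Cardiac phenotype vocabulary
#'
#' The packaged term list separating cardiac from extracardiac phenotype
#' terms. Matching is exact after case-folding: no ontology traversal is
#' performed, so terms absent from the list count as extracardiac. The list
#' ships at `system.file("extdata", "cardiac_terms.txt", package =
#' "cnvTriage")` and can be replaced or extended via `file`/`extra`.
#'
#' @param file optional path to a replacement term list (one term per line,
#'   `#` comments allowed).
#' @param extra optional character vector of additional terms.
#' @return character vector of case-folded cardiac terms.
#' @export
cardiacVocabulary <- function(file = NULL, extra = NULL) {
  file <- file %||% system.file("extdata", "cardiac_terms.txt",
                                package = "cnvTriage")
  terms <- readLines(file, warn = FALSE)
  terms <- trimws(sub("#.*$", "", terms))
  unique(tolower(c(terms[nzchar(terms)], extra)))
}

#' Classify a patient's phenotype profile
#'
#' `syndromic_chd` when the term list contains at least one cardiac and at
#' least one extracardiac term, `isolated_chd` when it contains cardiac
#' terms only, `no_chd` otherwise (including an empty list).
#'
#' @param terms character vector of phenotype terms (one patient), or a list
#'   of such vectors.
#' @param vocabulary cardiac term set from [cardiacVocabulary()].
#' @return factor over `syndromic_chd`, `isolated_chd`, `no_chd`.
#' @examples
#' v <- c("ventricular septal defect", "tetralogy of fallot")
#' classifyPatient(c("VSD", "Intellectual disability"), v) # no_chd ("VSD"
#' # is not in this two-term vocabulary); use cardiacVocabulary() in practice
#' @export
classifyPatient <- function(terms, vocabulary) {
  if (length(vocabulary) == 0L) abort("'vocabulary' must be non-empty")
  vocabulary <- tolower(vocabulary)
  if (!is.list(terms)) terms <- list(terms)
  out <- vapply(terms, function(tt) {
    tt <- tolower(trimws(tt))
    tt <- tt[nzchar(tt)]
    if (!length(tt)) return("no_chd")
    cardiac <- tt %in% vocabulary
    if (any(cardiac) && any(!cardiac)) "syndromic_chd"
    else if (any(cardiac)) "isolated_chd"
    else "no_chd"
  }, character(1L))
  factor(out, levels = c("syndromic_chd", "isolated_chd", "no_chd"))
}

#' Read a DECIPHER-style patient phenotype table
#'
#' TSV dialect `patient_id chrom start end copy_state terms` with phenotype
#' terms `;`-separated.
#'
#' @param file path to a TSV file.
#' @return data.frame with a list-column `terms`.
#' @export
readPhenotypePatients <- function(file) {
  df <- readTsv(file, c("patient_id", "chrom", "start", "end", "copy_state",
                        "terms"))
  df$copy_state <- normalizeCopyState(df$copy_state)
  df$terms <- lapply(strsplit(as.character(df$terms), ";", fixed = TRUE),
                     trimws)
  df
}

topTerms <- function(termLists, vocabulary, cardiac = TRUE, k = 5L) {
  tt <- tolower(trimws(unlist(termLists)))
  tt <- tt[nzchar(tt)]
  keep <- if (cardiac) tt %in% vocabulary else !(tt %in% vocabulary)
  tab <- table(tt[keep])
  if (!length(tab))
    return(data.frame(term = character(), count = integer()))
  df <- data.frame(term = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  # deterministic: count descending, then lexicographic
  df <- df[order(-df$count, df$term), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}

#' Phenotype spectrum of one CNV region
#'
#' Matches the patient table against the region (reciprocal overlap of at
#' least `minReciprocal`, same copy state by default), classifies each
#' matched patient with [classifyPatient()], and tallies the top-k cardiac
#' and extracardiac terms among syndromic patients. Percentages are half-up
#' to one decimal and undefined (`NA`) when no patient matches. Tied term
#' counts break lexicographically, so the tallies are stable under input
#' permutation.
#'
#' @param region single-interval `GRanges` with a `copyState` metadata
#'   column (a one-row [CnvCalls-class] works).
#' @param patients data.frame from [readPhenotypePatients()].
#' @param vocabulary cardiac term set from [cardiacVocabulary()].
#' @param minReciprocal inclusive reciprocal-overlap threshold (default 0.5).
#' @param matchCopyState require the patient CNV to share the region's copy
#'   state (default `TRUE`).
#' @param k tally length (default 5).
#' @return list with fields `region`, `copyState`, `nTotal`, `nSyndromic`,
#'   `nIsolated`, `pctSyndromic`, `pctIsolated`, `topExtracardiac`,
#'   `topCardiac`.
#' @export
regionSpectrum <- function(region, patients, vocabulary = cardiacVocabulary(),
                           minReciprocal = 0.5, matchCopyState = TRUE,
                           k = 5L) {
  if (length(region) != 1L) abort("'region' must be a single interval")
  state <- GenomicRanges::mcols(region)$copyState
  ro <- .ro1(as.character(GenomicRanges::seqnames(region)),
             GenomicRanges::start(region), GenomicRanges::end(region),
             normalizeChrom(patients$chrom), as.numeric(patients$start),
             as.numeric(patients$end))
  hit <- ro >= minReciprocal
  if (matchCopyState && !is.null(state))
    hit <- hit & patients$copy_state == as.character(state)
  matched <- patients[hit, , drop = FALSE]
  cls <- classifyPatient(matched$terms, vocabulary)
  nTotal <- nrow(matched)
  nSyn <- sum(cls == "syndromic_chd")
  nIso <- sum(cls == "isolated_chd")
  syn <- matched$terms[cls == "syndromic_chd"]
  list(region = formatRegion(region),
       copyState = if (is.null(state)) NA_character_ else as.character(state),
       nTotal = nTotal, nSyndromic = nSyn, nIsolated = nIso,
       pctSyndromic = pctHalfUp(nSyn, nTotal),
       pctIsolated = pctHalfUp(nIso, nTotal),
       topExtracardiac = topTerms(syn, vocabulary, cardiac = FALSE, k = k),
       topCardiac = topTerms(syn, vocabulary, cardiac = TRUE, k = k))
}

#' Spectrum table over several regions
#'
#' @param regions `GRanges` / [CnvCalls-class] with `copyState`.
#' @param patients,vocabulary,minReciprocal,matchCopyState,k passed to
#'   [regionSpectrum()].
#' @return data.frame with one row per region and the scalar spectrum
#'   fields; tallies are collapsed to `term (count)` strings.
#' @export
spectrumTable <- function(regions, patients,
                          vocabulary = cardiacVocabulary(),
                          minReciprocal = 0.5, matchCopyState = TRUE,
                          k = 5L) {
  rows <- lapply(seq_along(regions), function(i) {
    s <- regionSpectrum(regions[i], patients, vocabulary, minReciprocal,
                        matchCopyState, k)
    fmt <- function(df) paste(sprintf("%s (%d)", df$term, df$count),
                              collapse = "; ")
    data.frame(region = s$region, copyState = s$copyState,
               nTotal = s$nTotal, nSyndromic = s$nSyndromic,
               nIsolated = s$nIsolated, pctSyndromic = s$pctSyndromic,
               pctIsolated = s$pctIsolated,
               topExtracardiac = fmt(s$topExtracardiac),
               topCardiac = fmt(s$topCardiac), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differential disease genes between two phenotype groups
#'
#' Sorted set differences, e.g. disease genes seen in isolated-CHD carriers
#' of a region but absent from syndromic-CHD carriers in a study cohort.
#'
#' @param genesIsolated,genesSyndromic character vectors of symbols.
#' @return list with `isolatedOnly` and `syndromicOnly`, both sorted.
#' @export
differentialGenes <- function(genesIsolated, genesSyndromic) {
  a <- normalizeSymbols(genesIsolated)
  b <- normalizeSymbols(genesSyndromic)
  list(isolatedOnly = sort(setdiff(a, b)),
       syndromicOnly = sort(setdiff(b, a)))
}
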