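## Bundled case-study tables: a published 109-patient syndromic-CHD cohort
## whose printed counts serve as golden values for the pipeline.

fixtureFile <- function(name)
  system.file("extdata", name, package = "cnvTriage", mustWork = TRUE)

#' Bundled P/LP CNV table
#'
#' The case study's published CNV table: one row per reported CNV of the 24
#' patients with at least one pathogenic/likely pathogenic call, with the
#' three verdict columns (MVP category and score, curated-region verdict,
#' gene-evidence verdict), the published size, and the patient's cardiac
#' terms. Applying [consensusClassify()] to the verdict columns reproduces
#' the published count of 29 P/LP CNVs. `sizeConsistent` marks rows whose
#' published size agrees with their own published coordinates under the
#' `end - start` convention (a handful do not, most plausibly a genome-build
#' mixup in the source).
#'
#' @return a [CnvCalls-class] with metadata columns `regionLabel`,
#'   `sizePrintedMb`, `sizeConsistent`, `mvpScore`, `mvpCategory`,
#'   `decipherCategory`, `omimCategory`, `consensusPlp`, `cardiacTerms`.
#' @examples
#' tab <- casePlpCnvs()
#' sum(GenomicRanges::mcols(tab)$consensusPlp) # 29
#' @export
casePlpCnvs <- function() {
  df <- readTsv(fixtureFile("plp_cnv_table.tsv"))
  gr <- parseRegion(df$range)
  calls <- CnvCalls(df$patient, as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr), GenomicRanges::end(gr),
                    df$copy_state)
  mc <- GenomicRanges::mcols(calls)
  mc$regionLabel <- df$region
  mc$sizePrintedMb <- df$size_printed_mb
  mc$sizeConsistent <- df$size_consistent
  mc$mvpScore <- df$mvp_score
  mc$mvpCategory <- asCategory(df$mvp_category)
  mc$decipherCategory <- asCategory(df$decipher_category)
  mc$omimCategory <- asCategory(df$omim_category)
  mc$consensusPlp <- consensusClassify(mc$mvpCategory, mc$decipherCategory,
                                       mc$omimCategory)
  mc$cardiacTerms <- df$cardiac_terms
  GenomicRanges::mcols(calls) <- mc
  calls
}

#' Bundled phenotype-spectrum counts
#'
#' Published per-region syndromic / isolated CHD counts from a curated
#' patient database: `syn_n` of `syn_N` matched carriers are syndromic
#' (published percentage `syn_pct`), `iso_n` isolated (`iso_pct`, `NA` when
#' no percentage was published).
#'
#' @return data.frame with one row per region.
#' @export
caseSpectrumCounts <- function() readTsv(fixtureFile("spectrum_table.tsv"))

#' Bundled cohort cross-tabulation
#'
#' Published CHD-category (A-H) by primary-extracardiac-comorbidity counts
#' of the 109-patient case-study cohort.
#'
#' @return data.frame with class rows, system count columns, and a
#'   `representative_terms` column used by [caseCohort()].
#' @export
caseCrosstab <- function() readTsv(fixtureFile("cohort_crosstab.tsv"))

#' Patient-level expansion of the bundled cross-tabulation
#'
#' Expands [caseCrosstab()] into one row per patient (109 rows), assigning
#' each the class's representative cardiac-term combination and the cell's
#' extracardiac system, so that [summarizeCohort()] reproduces the published
#' marginals exactly.
#'
#' @return data.frame with columns `sample_id`, `sex`, `age`,
#'   `cardiac_terms` (list-column), `extracardiac_primary`.
#' @export
caseCohort <- function() {
  ct <- caseCrosstab()
  systems <- setdiff(names(ct), c("class", "representative_terms"))
  rows <- list()
  for (i in seq_len(nrow(ct))) for (s in systems) {
    n <- ct[[s]][i]
    if (n == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      class = ct$class[i], terms = ct$representative_terms[i], system = s,
      count = n, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  idx <- rep(seq_len(nrow(cells)), cells$count)
  out <- data.frame(
    sample_id = sprintf("C%03d", seq_along(idx)),
    sex = NA_character_, age = NA_real_,
    cardiac_terms = I(strsplit(cells$terms[idx], ";", fixed = TRUE)),
    extracardiac_primary = cells$system[idx],
    stringsAsFactors = FALSE)
  out
}

#' Published headline counts of the bundled case study
#'
#' The cohort-structure counts the case study reports: cohort size, excluded
#' aneuploidy/gross cases, raw and candidate CNV counts, and P/LP carriers.
#' These are inputs (a published table), not values computed by this
#' package.
#'
#' @return named list of integers.
#' @export
caseCounts <- function() {
  list(nPatients = 109L, nAneuploidy = 2L, nGross = 3L,
       nRawCnvs = 43L, nRawCarriers = 37L,
       nCandidateCnvs = 34L, nCandidateCarriers = 28L,
       nPlpCnvs = 29L, nPlpCarriers = 24L)
}
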