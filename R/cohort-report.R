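## Stage 6: cohort-level summaries — A-H CHD categorization, diagnostic
## yield, cross-tabulation against extracardiac systems, and CNV
## chromosome / size distributions.

#' Default A-H CHD category map
#'
#' Term sets for the eight-class congenital-heart-disease categorization
#' used in cohort tables: A septal defects (ASD, VSD, AVSD); B isolated
#' valve abnormalities (TR, MR, PS, MS, bicuspid aortic valve, supramitral
#' stenosing ring); C septal defects with valve abnormalities; D left
#' ventricular outflow-tract obstruction (AS, CoA); E isolated conotruncal
#' defects (TOF, DORV, TGA; PA joins the conotruncal set for class F);
#' F conotruncal defects with other heart defects; G heterotaxy syndrome;
#' H everything else (PAPVC, PDA, truncus arteriosus, ...). Abbreviations
#' and long forms are both listed; matching is exact after case-folding.
#'
#' @return named list of character vectors (classes A, B, D, E, G, H plus
#'   `conotruncal`, the E set extended by pulmonary atresia).
#' @export
chdCategoryMap <- function() {
  A <- c("asd", "vsd", "avsd", "atrial septal defect",
         "ventricular septal defect", "atrioventricular septal defect",
         "complete avsd", "complete atrioventricular septal defect")
  B <- c("tr", "mr", "ps", "ms", "pvs", "tricuspid regurgitation",
         "mitral regurgitation", "pulmonic stenosis", "pulmonary stenosis",
         "pulmonary valve stenosis", "mitral stenosis",
         "bicuspid aortic valve", "supramitral stenosing ring")
  D <- c("as", "coa", "aortic stenosis", "coarctation of the aorta",
         "aortic coarctation")
  E <- c("tof", "dorv", "tga", "tetralogy of fallot",
         "double outlet right ventricle", "anatomical dorv with tga",
         "transposition of the great arteries")
  G <- c("heterotaxy", "heterotaxy syndrome", "solitary dextrocardia")
  H <- c("papvc", "pas", "sv", "pda", "patent ductus arteriosus",
         "truncus arteriosus", "hypoplastic left heart syndrome",
         "hypoplastic left heart", "aortic regurgitation",
         "partial anomalous pulmonary venous connection",
         "pulmonary artery stenosis", "single ventricle", "pvs",
         "pulmonary valve stenosis")
  # recognized cardiac terms outside the A-G sets: they count as "other
  # heart defects" (triggering F beside a conotruncal term, else H)
  other <- c("raa", "right aortic arch", "dextrocardia",
             "abnormal origin of right coronary artery",
             "abnormal right coronary artery branch",
             "abnormal right ventricular muscle bundle",
             "left aortic arch with right subclavian artery voyage",
             "bilateral right atrium heterogeneity", "ventricular reversal")
  list(A = A, B = B, D = D, E = E, G = G, H = H, other = other,
       conotruncal = c(E, "pa", "pulmonary atresia"))
}

#' Assign the A-H CHD category
#'
#' Resolution order (each patient gets exactly one class): heterotaxy
#' dominates (G); a conotruncal defect with any other heart defect is a
#' compound conotruncal case (F), alone it is isolated conotruncal (E);
#' septal plus valve abnormalities combine to C; then D, B, A in turn; and
#' anything left (including unknown terms, which raise a warning) is H.
#' The precedence is configurable only through the term map; the order
#' itself reproduces the class assignments implied by published phenotype
#' strings (e.g. `{VSD} -> A`, `{VSD, MR} -> C`, `{TOF, RAA} -> F`).
#'
#' @param terms character vector of cardiac terms (one patient), or a list
#'   of such vectors.
#' @param map term map from [chdCategoryMap()].
#' @return factor over `A`..`H`.
#' @export
chdCategory <- function(terms, map = chdCategoryMap()) {
  if (!is.list(terms)) terms <- list(terms)
  known <- unique(tolower(unlist(map)))
  out <- vapply(terms, function(tt) {
    tt <- tolower(trimws(tt))
    tt <- tt[nzchar(tt)]
    if (!length(tt)) abort("cardiac term list must be non-empty")
    unknown <- setdiff(tt, known)
    if (length(unknown))
      warning("unmapped cardiac term(s): ", paste(unknown, collapse = ", "),
              call. = FALSE)
    inG <- any(tt %in% map$G)
    inCono <- tt %in% map$conotruncal
    inA <- any(tt %in% map$A)
    inB <- any(tt %in% map$B)
    inD <- any(tt %in% map$D)
    if (inG) return("G")
    if (any(inCono)) return(if (any(!inCono)) "F" else "E")
    if (inA && inB) return("C")
    if (inD) return("D")
    if (inB) return("B")
    if (inA) return("A")
    "H"
  }, character(1L))
  factor(out, levels = LETTERS[1:8])
}

#' Read a cohort phenotype table
#'
#' TSV dialect `sample_id sex age cardiac_terms extracardiac_primary` with
#' cardiac terms `;`-separated and `extracardiac_primary` the single main or
#' most severe extracardiac comorbidity.
#'
#' @param file path to a TSV file.
#' @return data.frame with a list-column `cardiac_terms`.
#' @export
readCohortTable <- function(file) {
  df <- readTsv(file, c("sample_id", "sex", "age", "cardiac_terms",
                        "extracardiac_primary"))
  df$cardiac_terms <- lapply(
    strsplit(as.character(df$cardiac_terms), ";", fixed = TRUE), trimws)
  df
}

#' Diagnostic yield of a triaged cohort
#'
#' The reportable-finding rate: carriers of at least one consensus-P/LP CNV
#' over patients remaining after aneuploidy/gross-aberration exclusion. The
#' `overallImbalance` companion counts any chromosomal imbalance — excluded
#' patients plus candidate-CNV carriers — over the full cohort.
#'
#' @param samples character vector of all patient ids.
#' @param excluded ids of patients flagged aneuploidy/gross (see
#'   [excludedPatients()]).
#' @param plpCarriers ids of patients with at least one consensus-P/LP CNV.
#' @return list with `numerator`, `denominator`, `pct` (half-up, 1 decimal;
#'   `NA` when the denominator is 0).
#' @examples
#' diagnosticYield(paste0("p", 1:109), paste0("p", 1:5), paste0("p", 6:29))
#' @export
diagnosticYield <- function(samples, excluded, plpCarriers) {
  samples <- unique(samples)
  excluded <- intersect(unique(excluded), samples)
  eligible <- setdiff(samples, excluded)
  num <- length(intersect(unique(plpCarriers), eligible))
  den <- length(eligible)
  list(numerator = num, denominator = den, pct = pctHalfUp(num, den))
}

#' @rdname diagnosticYield
#' @param candidateCarriers ids of patients carrying at least one candidate
#'   CNV (before pathogenicity classification).
#' @export
overallImbalance <- function(samples, excluded, candidateCarriers) {
  samples <- unique(samples)
  num <- length(intersect(
    union(unique(excluded), unique(candidateCarriers)), samples))
  list(numerator = num, denominator = length(samples),
       pct = pctHalfUp(num, length(samples)))
}

#' Cross-tabulate CHD categories against extracardiac systems
#'
#' One row per CHD class A-H, one column per extracardiac system, with the
#' printed-table conventions: row percentages use row totals, the Total
#' column's percentages use the cohort size, both half-up to one decimal.
#'
#' @param cohort data.frame from [readCohortTable()] (or any with
#'   `cardiac_terms` list-column and `extracardiac_primary`).
#' @param map passed to [chdCategory()].
#' @return list with `counts` (matrix, classes x systems, plus a `Total`
#'   column), `rowPct`, `totalPct` (per-class percentage of the cohort) and
#'   `columnPct` (per-system percentage of the cohort).
#' @export
summarizeCohort <- function(cohort, map = chdCategoryMap()) {
  cls <- chdCategory(cohort$cardiac_terms, map)
  sys <- as.character(cohort$extracardiac_primary)
  counts <- table(cls, factor(sys, levels = sort(unique(sys))))
  counts <- matrix(counts, nrow = nlevels(cls),
                   dimnames = list(levels(cls), colnames(counts)))
  total <- rowSums(counts)
  n <- nrow(cohort)
  rowPct <- sweep(counts, 1L, total, function(x, t) pctHalfUp(x, t))
  list(counts = cbind(Total = total, counts),
       rowPct = rowPct,
       totalPct = pctHalfUp(total, n),
       columnPct = pctHalfUp(colSums(counts), n),
       n = n)
}

#' Chromosome and size distributions of CNV calls
#'
#' Chromosome counts in canonical order (1-22, X, Y) and a size histogram
#' over right-open Mb bins `[e1, e2) ...`; calls at least as large as the
#' last edge land in an overflow bin with a warning.
#'
#' @param calls `GRanges` / [CnvCalls-class].
#' @param sizeBinsMb ascending bin edges in Mb
#'   (default `c(0, 1, 5, 10, 20, 40)`).
#' @return list with `chromCounts` (named integer vector over the
#'   chromosomes present) and `sizeHist` (data.frame `bin`, `count`).
#' @export
cnvDistributions <- function(calls, sizeBinsMb = c(0, 1, 5, 10, 20, 40)) {
  if (any(diff(sizeBinsMb) <= 0)) abort("'sizeBinsMb' must be ascending")
  chrom <- factor(as.character(GenomicRanges::seqnames(calls)),
                  levels = chromLevels())
  chromCounts <- table(chrom)
  chromCounts <- chromCounts[chromCounts > 0]
  mb <- lengthBp(calls) / 1e6
  labs <- paste0("[", sizeBinsMb[-length(sizeBinsMb)], ",",
                 sizeBinsMb[-1L], ")")
  idx <- findInterval(mb, sizeBinsMb)  # 0 below first edge (impossible >= 0)
  overflow <- sum(idx >= length(sizeBinsMb))
  if (overflow)
    warning(overflow, " CNV(s) larger than the last bin edge; ",
            "counted in the overflow bin")
  counts <- vapply(seq_along(labs), function(i) sum(idx == i), integer(1L))
  hist <- data.frame(bin = c(labs, sprintf(">=%s", sizeBinsMb[length(
    sizeBinsMb)])), count = c(counts, overflow), stringsAsFactors = FALSE)
  list(chromCounts = c(unclass(chromCounts)), sizeHist = hist)
}
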