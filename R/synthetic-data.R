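## Seeded generators producing every input the pipeline consumes, with
## planted ground truth, so all stages are testable without any download.
##
## The defaults encode the cohort structure this package's case study
## reports: 109 patients, 2 aneuploidies, 3 gross chromosomal aberrations,
## 43 raw CNVs in 37 carriers, 9 of them common in the population, leaving
## 34 candidate CNVs in 28 patients of which 29 CNVs in 24 patients are
## planted pathogenic/likely pathogenic.
##
## Generation runs on plain coordinate vectors and builds the S4 containers
## once per table; replicate studies (hundreds of seeds) stay cheap.

#' Approximate chromosome lengths
#'
#' Rounded autosome + X/Y lengths (bp) used by the simulator; any named
#' vector over `1..22, X, Y` can replace them.
#'
#' @return named numeric vector of lengths in bp.
#' @export
chromLengthsDefault <- function() {
  stats::setNames(1e6 * c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
                          135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48,
                          51, 155, 59),
                  chromLevels())
}

#' Simulation configuration
#'
#' Validated parameter set for [simulateCohort()]. Counts default to the
#' package's case-study cohort structure; set `pCarrier` (and optionally
#' `pAneuploidy`, `pGross`) to switch to a probabilistic mode where each
#' patient independently becomes a P/LP carrier with probability `pCarrier`
#' (used e.g. for binomial-recovery experiments).
#'
#' @param seed master seed; each generator component derives its own stream
#'   from it, so regenerating one table does not perturb the others.
#' @param nPatients cohort size.
#' @param nAneuploidy,nGross patients excluded for aneuploidy / gross
#'   aberrations (> `sizeThresholdMb`).
#' @param nRawCnvs,nRawCarriers CNV calls (excluding aneuploidy/gross
#'   events) and the patients carrying them.
#' @param nCommonCnvs calls planted as common in the population database.
#' @param nCandidateCnvs,nCandidateCarriers calls/patients surviving the
#'   common-CNV filter.
#' @param nPlpCnvs,nPlpCarriers planted consensus-P/LP calls and carriers.
#' @param pCarrier,pAneuploidy,pGross per-patient probabilities enabling the
#'   probabilistic mode (`pAneuploidy + pGross + pCarrier <= 1`).
#' @param popPerCommon,popPerRare population records planted per common /
#'   rare CNV (defaults 6 and 2, straddling the more-than-four rule).
#' @param nPopBackground unrelated small background population records.
#' @param minReciprocal,maxOccurrences,sizeThresholdMb filter parameters the
#'   plants are constructed against.
#' @param genesPerMb protein-coding gene density inside planted CNVs.
#' @param nBackgroundGenes genes placed outside any CNV.
#' @param nTools number of prioritization tools emulated.
#' @param nFullOverlapGenes,nThreeToolGenes genes planted in all tools /
#'   exactly `nTools - 1` tools.
#' @param spectrumTotal,spectrumSyndromic,spectrumIsolated planted counts
#'   for the phenotype-spectrum patient table of the first P/LP region.
#' @param chromLengths named chromosome lengths (bp).
#' @return validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nPatients = 109L, nAneuploidy = 2L,
                             nGross = 3L, nRawCnvs = 43L, nRawCarriers = 37L,
                             nCommonCnvs = 9L, nCandidateCnvs = 34L,
                             nCandidateCarriers = 28L, nPlpCnvs = 29L,
                             nPlpCarriers = 24L, pCarrier = NULL,
                             pAneuploidy = NULL, pGross = NULL,
                             popPerCommon = 6L, popPerRare = 2L,
                             nPopBackground = 50L, minReciprocal = 0.5,
                             maxOccurrences = 4L, sizeThresholdMb = 30,
                             genesPerMb = 2, nBackgroundGenes = 150L,
                             nTools = 4L, nFullOverlapGenes = 16L,
                             nThreeToolGenes = 30L, spectrumTotal = 745L,
                             spectrumSyndromic = 170L,
                             spectrumIsolated = 22L,
                             chromLengths = chromLengthsDefault()) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed %% 2e9)
  if (is.null(pCarrier)) {
    counts <- c("nPatients", "nAneuploidy", "nGross", "nRawCnvs",
                "nRawCarriers", "nCommonCnvs", "nCandidateCnvs",
                "nCandidateCarriers", "nPlpCnvs", "nPlpCarriers")
    for (k in counts) assertScalarNumber(cfg[[k]], k, 0)
    if (nAneuploidy + nGross + nRawCarriers > nPatients)
      abort("role counts exceed nPatients")
    if (nCommonCnvs != nRawCnvs - nCandidateCnvs)
      abort("nCommonCnvs must equal nRawCnvs - nCandidateCnvs")
    if (nCommonCnvs < nRawCarriers - nCandidateCarriers)
      abort("too few common CNVs for ", nRawCarriers - nCandidateCarriers,
            " common-only carriers")
    if (nPlpCnvs > nCandidateCnvs || nPlpCarriers > nCandidateCarriers)
      abort("planted P/LP counts exceed candidate counts")
    if (nPlpCnvs < nPlpCarriers)
      abort("nPlpCnvs must be at least nPlpCarriers")
    if (nCandidateCnvs - nPlpCnvs < nCandidateCarriers - nPlpCarriers)
      abort("not enough non-P/LP candidates for the non-P/LP carriers")
  } else {
    p <- c(pAneuploidy %||% 0, pGross %||% 0, pCarrier)
    if (any(p < 0 | p > 1) || sum(p) > 1)
      abort("probabilities must lie in [0, 1] and sum to at most 1")
  }
  if (spectrumSyndromic + spectrumIsolated > spectrumTotal)
    abort("spectrum counts exceed spectrumTotal")
  structure(cfg, class = "simulationConfig")
}

# independent RNG stream per generator component
withStream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((cfg$seed + offset) %% 2000000000)
  expr
}

# one random placement of sizeBp on a random chromosome, rejected while it
# reciprocally overlaps any interval in the plain-vector avoid set by more
# than maxRo; returns list(chrom, start, end)
randPlace <- function(sizeBp, chromLengths, aChrom = character(),
                      aStart = numeric(), aEnd = numeric(), maxRo = 0) {
  for (try in 1:200) {
    chrom <- sample(names(chromLengths), 1L)
    lim <- chromLengths[[chrom]] - sizeBp - 2e6
    if (lim < 1e6) next
    start <- floor(stats::runif(1L, 1e6, lim))
    if (!length(aChrom) ||
        max(.ro1(chrom, start, start + sizeBp, aChrom, aStart, aEnd)) <=
        maxRo)
      return(list(chrom = chrom, start = start, end = start + sizeBp))
  }
  abort("could not place a CNV without overlap; lower the CNV count")
}

# jittered copies of (chrom, start, end): shift and resize within +/- frac
# of the length, keeping reciprocal overlap with the template far above 0.5
jitterCoords <- function(chrom, start, end, n = 1L, frac = 0.05) {
  len <- end - start
  shift <- floor(stats::runif(n, -frac, frac) * len)
  grow <- floor(stats::runif(n, -frac, frac) * len)
  s <- pmax(1, start + shift)
  list(chrom = rep(chrom, n), start = s, end = s + len + grow)
}

#' Simulate a population CNV database around planted templates
#'
#' Emits `popPerCommon` jittered, same-state records per common template
#' (reciprocal overlap well above 0.5) and `popPerRare` per rare template,
#' plus unrelated small background records, so that [isCommon()] flags
#' exactly the common templates under the strict more-than-`maxOccurrences`
#' rule.
#'
#' @param templates a [CnvCalls-class] (or `GRanges` with `copyState`).
#' @param common logical vector, one per template.
#' @param popPerCommon,popPerRare records per template (common must exceed
#'   `maxOccurrences` of the filter; rare must not).
#' @param nBackground unrelated background records.
#' @param chromLengths named chromosome lengths.
#' @param seed RNG seed.
#' @return `GRanges` with `accession` and `copyState` columns.
#' @export
simulatePopdb <- function(templates, common, popPerCommon = 6L,
                          popPerRare = 2L, nBackground = 50L,
                          chromLengths = chromLengthsDefault(), seed = 1L) {
  cfg <- list(seed = as.integer(seed %% 2e9))
  tChrom <- as.character(GenomicRanges::seqnames(templates))
  tStart <- GenomicRanges::start(templates)
  tEnd <- GenomicRanges::end(templates)
  tState <- as.character(GenomicRanges::mcols(templates)$copyState)
  withStream(cfg, 0L, {
    chrom <- character(); start <- numeric(); end <- numeric()
    states <- character()
    for (i in seq_along(tChrom)) {
      nRec <- if (common[i]) popPerCommon else popPerRare
      if (nRec == 0L) next
      jit <- jitterCoords(tChrom[i], tStart[i], tEnd[i], nRec)
      chrom <- c(chrom, jit$chrom)
      start <- c(start, jit$start)
      end <- c(end, jit$end)
      states <- c(states, rep(tState[i], nRec))
    }
    for (j in seq_len(nBackground)) {
      sz <- floor(stats::runif(1L, 5e3, 2e4))
      pl <- randPlace(sz, chromLengths)
      chrom <- c(chrom, pl$chrom)
      start <- c(start, pl$start)
      end <- c(end, pl$end)
      states <- c(states, sample(c("deletion", "duplication", "both"), 1L))
    }
    gr <- newInterval(chrom, start, end)
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
      accession = sprintf("essv%06d", seq_along(gr)),
      copyState = states)
    gr
  })
}

.extracardiacPool <- c(
  "Intellectual disability", "Micrognathia", "Low-set ears", "Hypotonia",
  "Microcephaly", "Hypertelorism", "Global developmental delay",
  "Small for gestational age", "Cleft palate",
  "Feeding difficulties in infancy", "Cryptorchidism", "Hydrocephalus")

.cardiacPool <- c(
  "Ventricular septal defect", "Atrial septal defect",
  "Tetralogy of Fallot", "Patent ductus arteriosus", "Pulmonic stenosis",
  "Atrioventricular canal defect", "Abnormal heart morphology")

#' Simulate a full CNV cohort with planted ground truth
#'
#' Generates every table the pipeline consumes — patient CNV calls (with MVP
#' scores attached), a population database, curated-region and gene-evidence
#' annotation sources constructed so the planted P/LP calls (and only they)
#' satisfy the any-of-three consensus, a gene model tiling the CNVs,
#' per-tool priority lists with a planted overlap structure, and a
#' phenotype-spectrum patient table with planted syndromic/isolated counts —
#' together with the ground truth needed to verify full-pipeline recovery.
#' Planted CNVs are pairwise disjoint, so population records, curated
#' regions and genes of one CNV can never leak onto another and every
#' planted label is recoverable exactly.
#'
#' @param config a [simulationConfig()].
#' @param components which tables to generate (subset of
#'   `calls`, `popdb`, `annotations`, `genes`, `tools`, `spectrum`);
#'   trimming speeds up large replicate studies.
#' @return list of class `simulatedCohort` with elements `samples`, `calls`,
#'   `popdb`, `decipherRegions`, `omimMap`, `geneModel`, `toolLists`,
#'   `patients` (spectrum table), `spectrumRegion`, `truth` and `config`.
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 7),
#'                       components = c("calls", "popdb"))
#' length(sim$calls)
#' @export
simulateCohort <- function(config = simulationConfig(),
                           components = c("calls", "popdb", "annotations",
                                          "genes", "tools", "spectrum")) {
  stopifnot(inherits(config, "simulationConfig"))
  components <- match.arg(components, several.ok = TRUE,
                          choices = c("calls", "popdb", "annotations",
                                      "genes", "tools", "spectrum"))
  cl <- config$chromLengths
  samples <- sprintf("S%03d", seq_len(config$nPatients))
  out <- list(samples = samples, config = config)

  probMode <- !is.null(config$pCarrier)
  roles <- withStream(config, 0L, {
    shuffled <- sample(samples)
    if (probMode) {
      u <- stats::runif(config$nPatients)
      pA <- config$pAneuploidy %||% 0
      pG <- config$pGross %||% 0
      role <- ifelse(u < pA, "aneuploidy",
                     ifelse(u < pA + pG, "gross",
                            ifelse(u < pA + pG + config$pCarrier,
                                   "plp", "none")))
      list(aneuploidy = samples[role == "aneuploidy"],
           gross = samples[role == "gross"],
           carriers = samples[role == "plp"],
           plpCarriers = samples[role == "plp"])
    } else {
      idx <- 0L
      take <- function(n) {
        sel <- shuffled[idx + seq_len(n)]
        idx <<- idx + n
        sel
      }
      list(aneuploidy = take(config$nAneuploidy),
           gross = take(config$nGross),
           carriers = take(config$nRawCarriers))
    }
  })

  calls <- withStream(config, 1L, {
    sampleV <- character(); chromV <- character()
    startV <- numeric(); endV <- numeric()
    stateV <- character(); aneuV <- logical(); classV <- character()
    addCall <- function(sample, chrom, start, end, state, aneu = FALSE,
                        class = "candidate") {
      sampleV <<- c(sampleV, sample); chromV <<- c(chromV, chrom)
      startV <<- c(startV, start); endV <<- c(endV, end)
      stateV <<- c(stateV, state); aneuV <<- c(aneuV, aneu)
      classV <<- c(classV, class)
    }
    # complete pairwise disjointness keeps every planted label recoverable
    pChrom <- character(); pStart <- numeric(); pEnd <- numeric()
    place <- function(sizeBp) {
      pl <- randPlace(sizeBp, cl, pChrom, pStart, pEnd, maxRo = 0)
      pChrom <<- c(pChrom, pl$chrom)
      pStart <<- c(pStart, pl$start)
      pEnd <<- c(pEnd, pl$end)
      pl
    }
    addPlaced <- function(sample, sizeBp, class, state =
                            sample(c("deletion", "duplication"), 1L)) {
      pl <- place(sizeBp)
      addCall(sample, pl$chrom, pl$start, pl$end, state, class = class)
    }
    for (s in roles$aneuploidy) {
      chrom <- sample(names(cl), 1L)
      addCall(s, chrom, 1, cl[[chrom]],
              sample(c("deletion", "duplication"), 1L), aneu = TRUE,
              class = "aneuploidy")
    }
    for (s in roles$gross)
      addPlaced(s, floor(stats::runif(1L, config$sizeThresholdMb + 2,
                                      config$sizeThresholdMb + 10) * 1e6),
                "gross")
    # gross exclusion is patient-level: give the first gross patient an
    # additional sub-threshold call that must also drop
    if (length(roles$gross))
      addPlaced(roles$gross[1L], 3.6e6, "gross_extra", "duplication")
    if (probMode) {
      for (s in roles$carriers)
        addPlaced(s, floor(10^stats::runif(1L, log10(0.2e6), log10(26e6))),
                  "plp")
    } else {
      nCommonOnly <- config$nRawCarriers - config$nCandidateCarriers
      commonOnly <- roles$carriers[seq_len(nCommonOnly)]
      candCarriers <- setdiff(roles$carriers, commonOnly)
      plpCarriers <- candCarriers[seq_len(config$nPlpCarriers)]
      nonPlpCarriers <- setdiff(candCarriers, plpCarriers)
      owner <- c(plpCarriers,
                 sample(plpCarriers, config$nPlpCnvs - config$nPlpCarriers,
                        replace = TRUE))
      for (s in owner)
        addPlaced(s, floor(10^stats::runif(1L, log10(0.2e6), log10(26e6))),
                  "plp")
      nExtraNonPlp <- (config$nCandidateCnvs - config$nPlpCnvs) -
        length(nonPlpCarriers)
      owner <- c(nonPlpCarriers,
                 if (nExtraNonPlp > 0) sample(candCarriers, nExtraNonPlp,
                                              replace = TRUE))
      for (s in owner)
        addPlaced(s, floor(10^stats::runif(1L, log10(0.2e6), log10(10e6))),
                  "benign_candidate")
      owner <- c(commonOnly,
                 if (config$nCommonCnvs > nCommonOnly)
                   sample(candCarriers, config$nCommonCnvs - nCommonOnly,
                          replace = TRUE))
      for (s in owner)
        addPlaced(s, floor(stats::runif(1L, 0.1e6, 1e6)), "common")
      roles$plpCarriers <- plpCarriers
      roles$candCarriers <- candCarriers
    }
    calls <- CnvCalls(sampleV, chromV, startV, endV, stateV,
                      aneuploidy = aneuV)
    GenomicRanges::mcols(calls)$cnvId <-
      sprintf("CNV%03d", seq_along(calls))
    GenomicRanges::mcols(calls)$class <- classV
    calls
  })
  cls <- GenomicRanges::mcols(calls)$class
  out$calls <- calls
  out$truth <- list(
    aneuploidyPatients = sort(roles$aneuploidy),
    grossPatients = sort(roles$gross),
    commonCnvIds = GenomicRanges::mcols(calls)$cnvId[cls == "common"],
    candidateCnvIds = GenomicRanges::mcols(calls)$cnvId[
      cls %in% c("plp", "benign_candidate")],
    plpCnvIds = GenomicRanges::mcols(calls)$cnvId[cls == "plp"],
    plpCarriers = sort(unique(sampleId(calls)[cls == "plp"])),
    candidateCarriers = sort(unique(sampleId(calls)[
      cls %in% c("plp", "benign_candidate")])))

  if ("popdb" %in% components) {
    nonAneu <- calls[cls != "aneuploidy"]
    out$popdb <- simulatePopdb(
      nonAneu, GenomicRanges::mcols(nonAneu)$class == "common",
      popPerCommon = config$popPerCommon, popPerRare = config$popPerRare,
      nBackground = config$nPopBackground, chromLengths = cl,
      seed = config$seed + 104729L)
  }

  if ("annotations" %in% components)
    out <- simAnnotations(out, config)
  if (any(c("genes", "annotations", "tools") %in% components))
    out <- simGenes(out, config)
  if ("annotations" %in% components)  # omim map needs the gene model
    out <- simOmim(out, config)
  if ("tools" %in% components)
    out <- simTools(out, config)
  if ("spectrum" %in% components)
    out <- simSpectrum(out, config)
  structure(out, class = "simulatedCohort")
}

# MVP scores + curated-region table; decides each planted P/LP call's
# evidence pattern (which of the three sources carries it)
simAnnotations <- function(out, config) {
  calls <- out$calls
  cls <- GenomicRanges::mcols(calls)$class
  cChrom <- as.character(GenomicRanges::seqnames(calls))
  cStart <- GenomicRanges::start(calls)
  cEnd <- GenomicRanges::end(calls)
  withStream(config, 2L, {
    n <- length(calls)
    band <- function(lo, hi, k = 1L) stats::runif(k, lo, hi - 1e-6)
    score <- band(0, 0.14, n)  # default: benign band
    pattern <- rep("none", n)
    isPlp <- cls == "plp"
    pattern[isPlp] <- sample(c("mvp", "decipher", "omim", "all"),
                             sum(isPlp), replace = TRUE)
    mvpCarrying <- isPlp & pattern %in% c("mvp", "all")
    score[mvpCarrying] <- ifelse(stats::runif(sum(mvpCarrying)) < 0.5,
                                 band(0.5, 0.75, sum(mvpCarrying)),
                                 band(0.75, 1, sum(mvpCarrying)))
    rChrom <- character(); rStart <- numeric(); rEnd <- numeric()
    regCat <- character()
    addRegion <- function(i, category) {
      jit <- jitterCoords(cChrom[i], cStart[i], cEnd[i])
      rChrom <<- c(rChrom, jit$chrom)
      rStart <<- c(rStart, jit$start)
      rEnd <<- c(rEnd, jit$end)
      regCat <<- c(regCat, category)
    }
    for (i in which(isPlp & pattern %in% c("decipher", "all")))
      addRegion(i, sample(c("pathogenic", "likely_pathogenic"), 1L))
    # a few benign curated regions over non-P/LP candidates: they must not
    # flip the consensus
    for (i in utils::head(which(cls == "benign_candidate"), 2L))
      addRegion(i, "likely_benign")
    gr <- newInterval(rChrom, rStart, rEnd)
    GenomicRanges::mcols(gr)$category <- factor(regCat,
                                                pathogenicityLevels())
    GenomicRanges::mcols(calls)$mvpScore <- round(score, 3)
    GenomicRanges::mcols(calls)$pattern <- pattern
    out$calls <- calls
    out$decipherRegions <- gr
    out
  })
}

# gene model tiling every candidate CNV with its own protein-coding genes
simGenes <- function(out, config) {
  calls <- out$calls
  cls <- GenomicRanges::mcols(calls)$class
  cChrom <- as.character(GenomicRanges::seqnames(calls))
  cStart <- GenomicRanges::start(calls)
  cEnd <- GenomicRanges::end(calls)
  cId <- GenomicRanges::mcols(calls)$cnvId
  withStream(config, 3L, {
    gChrom <- character(); gStart <- numeric(); gEnd <- numeric()
    gBio <- character(); gCnv <- character()
    for (i in which(cls %in% c("plp", "benign_candidate"))) {
      nGenes <- max(2L, floor(config$genesPerMb *
                                (cEnd[i] - cStart[i]) / 1e6))
      bounds <- floor(seq(cStart[i] + 10, cEnd[i] - 10,
                          length.out = nGenes + 1L))
      bio <- ifelse(stats::runif(nGenes) < 0.9, "protein_coding", "other")
      bio[1L] <- "protein_coding"  # every CNV keeps >= 1 coding gene
      gChrom <- c(gChrom, rep(cChrom[i], nGenes))
      gStart <- c(gStart, bounds[-(nGenes + 1L)] + 1)
      gEnd <- c(gEnd, bounds[-1L] - 1)
      gBio <- c(gBio, bio)
      gCnv <- c(gCnv, rep(cId[i], nGenes))
    }
    for (b in seq_len(config$nBackgroundGenes)) {
      pl <- randPlace(floor(stats::runif(1L, 2e4, 2e5)),
                      config$chromLengths, cChrom, cStart, cEnd, maxRo = 0)
      gChrom <- c(gChrom, pl$chrom)
      gStart <- c(gStart, pl$start)
      gEnd <- c(gEnd, pl$end)
      gBio <- c(gBio, "protein_coding")
      gCnv <- c(gCnv, NA_character_)
    }
    gr <- newInterval(gChrom, gStart, gEnd)
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
      symbol = sprintf("G%05d", seq_along(gr)), biotype = gBio, cnvId = gCnv)
    out$geneModel <- gr
    out
  })
}

# OMIM-style map: disease genes inside omim-carried P/LP calls, a sprinkle
# of phenotype genes, background disease genes outside any CNV
simOmim <- function(out, config) {
  calls <- out$calls
  gm <- out$geneModel
  pattern <- GenomicRanges::mcols(calls)$pattern
  gmCnv <- GenomicRanges::mcols(gm)$cnvId
  gmSym <- GenomicRanges::mcols(gm)$symbol
  gmBio <- GenomicRanges::mcols(gm)$biotype
  withStream(config, 4L, {
    genes <- character()
    assoc <- character()
    for (i in which(pattern %in% c("omim", "all"))) {
      pc <- gmSym[!is.na(gmCnv) &
                    gmCnv == GenomicRanges::mcols(calls)$cnvId[i] &
                    gmBio == "protein_coding"]
      if (!length(pc)) next
      genes <- c(genes, pc[1L])
      assoc <- c(assoc, "disease")
      if (length(pc) > 1L && stats::runif(1L) < 0.5) {
        genes <- c(genes, pc[2L])
        assoc <- c(assoc, "phenotype")
      }
    }
    bg <- gmSym[is.na(gmCnv)]
    extra <- sample(bg, min(20L, length(bg)))
    genes <- c(genes, extra)
    assoc <- c(assoc, sample(c("disease", "phenotype"), length(extra),
                             replace = TRUE))
    out$omimMap <- data.frame(gene = genes, association = assoc,
                              stringsAsFactors = FALSE)
    out
  })
}

# per-tool priority lists with a planted k-of-n overlap structure over the
# genes inside planted P/LP CNVs
simTools <- function(out, config) {
  gm <- out$geneModel
  plpIds <- out$truth$plpCnvIds
  withStream(config, 5L, {
    universe <- unique(GenomicRanges::mcols(gm)$symbol[
      GenomicRanges::mcols(gm)$cnvId %in% plpIds &
        GenomicRanges::mcols(gm)$biotype == "protein_coding"])
    need <- config$nFullOverlapGenes + config$nThreeToolGenes + 10L
    if (length(universe) < need)
      abort("planted CNVs contain too few genes (", length(universe),
            ") for the requested overlap structure; raise genesPerMb")
    universe <- sample(universe)
    full <- universe[seq_len(config$nFullOverlapGenes)]
    three <- universe[config$nFullOverlapGenes +
                        seq_len(config$nThreeToolGenes)]
    rest <- universe[-seq_len(config$nFullOverlapGenes +
                                config$nThreeToolGenes)]
    nT <- config$nTools
    toolNames <- c("varelect", "ova", "amelie", "toppgene")[seq_len(nT)]
    sets <- stats::setNames(rep(list(character()), nT), toolNames)
    for (t in toolNames) sets[[t]] <- full
    for (g in three) {
      drop <- sample(nT, 1L)
      for (t in toolNames[-drop]) sets[[t]] <- c(sets[[t]], g)
    }
    for (g in rest) {
      k <- sample(0:(nT - 2L), 1L)
      if (k > 0) for (t in sample(toolNames, k)) sets[[t]] <- c(sets[[t]], g)
    }
    toolLists <- lapply(toolNames, function(t) {
      if (t == "toppgene") {
        inSet <- universe %in% sets[[t]]
        data.frame(
          gene = universe,
          p = ifelse(inSet, stats::runif(length(universe), 0, 0.049),
                     stats::runif(length(universe), 0.05, 1)),
          interactions = ifelse(inSet,
                                sample(20:120, length(universe), TRUE),
                                sample(0:19, length(universe), TRUE)),
          stringsAsFactors = FALSE)
      } else {
        data.frame(gene = sets[[t]],
                   score = round(stats::runif(length(sets[[t]]), 1, 50), 2),
                   stringsAsFactors = FALSE)
      }
    })
    names(toolLists) <- toolNames
    out$toolLists <- toolLists
    out$truth$toolSets <- lapply(sets, sort)
    out$truth$fullOverlapGenes <- sort(full)
    out$truth$threeToolGenes <- sort(three)
    out
  })
}

# DECIPHER-style phenotype patient table with planted syndromic / isolated /
# non-cardiac counts, all carrying a CNV matching the first planted P/LP call
simSpectrum <- function(out, config) {
  calls <- out$calls
  plpIdx <- which(GenomicRanges::mcols(calls)$class == "plp")
  if (!length(plpIdx)) {
    out$patients <- NULL
    return(out)
  }
  region <- calls[plpIdx[1L]]
  withStream(config, 6L, {
    nTot <- config$spectrumTotal
    grp <- c(rep("syndromic", config$spectrumSyndromic),
             rep("isolated", config$spectrumIsolated),
             rep("none", nTot - config$spectrumSyndromic -
                   config$spectrumIsolated))
    jit <- jitterCoords(as.character(GenomicRanges::seqnames(region)),
                        GenomicRanges::start(region),
                        GenomicRanges::end(region), nTot)
    terms <- vapply(grp, function(g) paste(switch(g,
      syndromic = c(sample(.cardiacPool, sample(1:3, 1L)),
                    sample(.extracardiacPool, sample(1:3, 1L))),
      isolated = sample(.cardiacPool, sample(1:2, 1L)),
      none = sample(.extracardiacPool, sample(1:3, 1L))),
      collapse = ";"), character(1L))
    df <- data.frame(
      patient_id = sprintf("D%05d", seq_len(nTot)),
      chrom = jit$chrom, start = jit$start, end = jit$end,
      copy_state = copyState(region),
      terms = unname(terms), stringsAsFactors = FALSE)
    df$terms <- lapply(strsplit(df$terms, ";", fixed = TRUE), trimws)
    out$patients <- df
    out$spectrumRegion <- region
    out$truth$spectrum <- list(nTotal = nTot,
                               nSyndromic = config$spectrumSyndromic,
                               nIsolated = config$spectrumIsolated)
    out
  })
}
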