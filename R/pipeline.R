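## End-to-end pipeline: filter -> classify -> annotate -> prioritize ->
## spectrum -> summarize, with TSV/JSON outputs carrying a config hash so
## reruns on identical inputs are byte-identical.

#' Pipeline configuration
#'
#' Collects every stage threshold with its documented default. Unknown keys
#' are rejected by construction (the function signature is the schema).
#'
#' @param sizeThresholdMb gross-aberration threshold in Mb (default 30).
#' @param minReciprocal strict reciprocal-overlap threshold of the
#'   population filter (default 0.5).
#' @param maxOccurrences strict occurrence threshold of the population
#'   filter (default 4).
#' @param matchCopyState require matching copy state in the population
#'   filter (default `TRUE`).
#' @param aneuploidySpanFraction chromosome fraction for the span-based
#'   aneuploidy flag (default 0.9).
#' @param mvpCutpoints four ascending MVP category cut-points.
#' @param decipherMinReciprocal strict overlap threshold of the
#'   curated-region verdict (default 0.5).
#' @param spectrumMinReciprocal inclusive overlap threshold of the spectrum
#'   matcher (default 0.5).
#' @param geneMode `"any_overlap"` or `"contained"` CNV-to-gene mapping.
#' @param pMax,minInteractions network-tool thresholds (defaults 0.05, 20).
#' @param minTools consensus membership threshold; `NULL` means
#'   "all tools but one".
#' @param sizeBinsMb size-histogram edges in Mb.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(sizeThresholdMb = 30, minReciprocal = 0.5,
                           maxOccurrences = 4, matchCopyState = TRUE,
                           aneuploidySpanFraction = 0.9,
                           mvpCutpoints = c(0.14, 0.18, 0.50, 0.75),
                           decipherMinReciprocal = 0.5,
                           spectrumMinReciprocal = 0.5,
                           geneMode = c("any_overlap", "contained"),
                           pMax = 0.05, minInteractions = 20,
                           minTools = NULL,
                           sizeBinsMb = c(0, 1, 5, 10, 20, 40)) {
  geneMode <- match.arg(geneMode)
  cfg <- as.list(environment())
  structure(cfg, class = "pipelineConfig")
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
}

#' Run the full triage pipeline
#'
#' Executes filter, classify, annotate, prioritize, spectrum and summarize
#' in order, writing one TSV per stage plus a machine-readable
#' `summary.json` into `outDir`. Inputs may be given as objects or file
#' paths (paths are read with the matching reader). Stages whose inputs are
#' absent are skipped. The pipeline itself is deterministic: two runs on
#' identical inputs produce identical outputs.
#'
#' @param calls [CnvCalls-class] or path for [readCnvCalls()]; MVP scores
#'   are taken from an `mvpScore` metadata column when present.
#' @param outDir output directory (created if needed).
#' @param popdb population records or path ([readPopulationCnvs()]).
#' @param decipherRegions curated regions or path ([readDecipherRegions()]).
#' @param omimMap gene-association map or path ([readOmimMap()]).
#' @param geneModel gene model or path ([readGeneModel()]).
#' @param toolLists named list of per-tool data.frames, or named character
#'   vector of paths ([readToolGeneLists()]); a list with `p` and
#'   `interactions` columns is thresholded via [thresholdToppGene()], other
#'   lists are consumed as already prioritized.
#' @param phenotypePatients spectrum patient table or path
#'   ([readPhenotypePatients()]).
#' @param samples full patient roster (defaults to the samples in `calls`).
#' @param mvpScores optional numeric vector of MVP scores aligned with
#'   `calls` (overrides the metadata column).
#' @param config a [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `report` ([FilterReport-class]),
#'   `annotated`, `plpCnvs`, `geneUniverse`, `consensus`, `spectrum` and
#'   `summary`.
#' @export
runPipeline <- function(calls, outDir, popdb = NULL, decipherRegions = NULL,
                        omimMap = NULL, geneModel = NULL, toolLists = NULL,
                        phenotypePatients = NULL, samples = NULL,
                        mvpScores = NULL, config = pipelineConfig(),
                        quiet = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (!quiet) message(...)
  if (is.character(calls)) calls <- readCnvCalls(calls)
  if (is.character(popdb)) popdb <- readPopulationCnvs(popdb)
  if (is.character(decipherRegions))
    decipherRegions <- readDecipherRegions(decipherRegions)
  if (is.character(omimMap)) omimMap <- readOmimMap(omimMap)
  if (is.character(geneModel)) geneModel <- readGeneModel(geneModel)
  if (is.character(toolLists)) toolLists <- readToolGeneLists(toolLists)
  if (is.character(phenotypePatients))
    phenotypePatients <- readPhenotypePatients(phenotypePatients)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(tool = paste0("cnvTriage ",
                          as.character(utils::packageVersion("cnvTriage"))),
            config_hash = configHash(unclass(config)))
  samples <- unique(samples %||% sampleId(calls))

  say("stage filter: ", length(calls), " calls, ", length(samples),
      " patients")
  report <- stageTry("filter", filterCohort(
    calls, popdb, samples = samples,
    sizeThresholdMb = config$sizeThresholdMb,
    aneuploidySpanFraction = config$aneuploidySpanFraction,
    minReciprocal = config$minReciprocal,
    maxOccurrences = config$maxOccurrences,
    matchCopyState = config$matchCopyState))
  writeTsv(excludedPatients(report),
           file.path(outDir, "excluded_patients.tsv"), meta)
  writeTsv(cnvCallsToDf(excludedCnvs(report)),
           file.path(outDir, "excluded_cnvs.tsv"), meta)
  cand <- candidateCnvs(report)

  say("stage classify: ", length(cand), " candidate CNVs")
  scores <- mvpScores %||% GenomicRanges::mcols(cand)$mvpScore
  annotated <- stageTry("classify", classifyCnvs(
    cand, mvpScore = scores, decipherRegions = decipherRegions,
    omimMap = omimMap, geneModel = geneModel,
    cutpoints = config$mvpCutpoints,
    minReciprocal = config$decipherMinReciprocal))
  writeTsv(cnvCallsToDf(annotated),
           file.path(outDir, "annotated_cnvs.tsv"), meta)
  plp <- annotated[GenomicRanges::mcols(annotated)$consensusPlp]

  universe <- NULL
  if (!is.null(geneModel)) {
    say("stage annotate: mapping ", length(plp), " P/LP CNVs to genes")
    universe <- stageTry("annotate",
                         cohortGeneUniverse(plp, geneModel,
                                            mode = config$geneMode))
    writeTsv(data.frame(gene = universe$universe),
             file.path(outDir, "gene_universe.tsv"), meta)
  }

  consensus <- NULL
  if (!is.null(toolLists)) {
    say("stage prioritize: ", length(toolLists), " tool lists")
    consensus <- stageTry("prioritize", {
      sets <- lapply(toolLists, function(tl) {
        if (all(c("p", "interactions") %in% names(tl)))
          thresholdToppGene(tl, pMax = config$pMax,
                            minInteractions = config$minInteractions)
        else thresholdToolList(tl)
      })
      consensusGenes(sets, minTools = config$minTools %||%
                       max(1L, length(sets) - 1L))
    })
    writeTsv(consensus$counts, file.path(outDir, "gene_consensus.tsv"),
             meta)
  }

  spectrum <- NULL
  if (!is.null(phenotypePatients) && length(plp)) {
    say("stage spectrum: ", nrow(phenotypePatients), " database patients")
    spectrum <- stageTry("spectrum", spectrumTable(
      plp, phenotypePatients,
      minReciprocal = config$spectrumMinReciprocal))
    writeTsv(spectrum, file.path(outDir, "phenotype_spectrum.tsv"), meta)
  }

  say("stage summarize")
  plpCarriers <- unique(sampleId(plp))
  yield <- diagnosticYield(samples, excludedPatients(report)$sampleId,
                           plpCarriers)
  # any chromosomal imbalance: excluded patients plus carriers of any raw
  # call (common CNVs still count as imbalances here)
  imbalance <- overallImbalance(samples, excludedPatients(report)$sampleId,
                                unique(sampleId(calls)))
  dist <- if (length(cand)) cnvDistributions(cand, config$sizeBinsMb)
  else NULL
  summary <- list(
    n_patients = length(samples),
    n_excluded_patients = nrow(excludedPatients(report)),
    n_candidate_cnvs = length(cand),
    n_plp_cnvs = length(plp),
    n_plp_patients = length(plpCarriers),
    yield = yield, overall_imbalance = imbalance,
    chromosome_counts = as.list(dist$chromCounts %||% integer()),
    config_hash = unname(meta[["config_hash"]]))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, annotated = annotated, plpCnvs = plp,
                 geneUniverse = universe, consensus = consensus,
                 spectrum = spectrum, summary = summary))
}
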