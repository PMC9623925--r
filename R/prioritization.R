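## Stage 4: threshold per-tool outputs and intersect priority lists.

#' Threshold ToppGene/ToppNet output
#'
#' Keeps genes with a functional-enrichment p-value strictly below `pMax`
#' and a network interaction count of at least `minInteractions` (inclusive),
#' the published rule "p-value < 0.05 and interaction count >= 20". Entries
#' missing either score are dropped with a warning.
#'
#' @param entries data.frame with columns `gene`, `p`, `interactions`.
#' @param pMax strict p-value cut-off (default 0.05).
#' @param minInteractions inclusive interaction-count cut-off (default 20).
#' @return character vector of prioritized gene symbols.
#' @export
thresholdToppGene <- function(entries, pMax = 0.05, minInteractions = 20) {
  assertScalarNumber(pMax, "pMax", 0, 1)
  assertScalarNumber(minInteractions, "minInteractions", 0)
  need <- c("gene", "p", "interactions")
  if (!all(need %in% names(entries)))
    abort("'entries' needs columns ", paste(need, collapse = ", "))
  miss <- is.na(entries$p) | is.na(entries$interactions)
  if (any(miss)) {
    warning(sum(miss), " entr", if (sum(miss) == 1) "y" else "ies",
            " missing a score; excluded")
    entries <- entries[!miss, , drop = FALSE]
  }
  keep <- entries$p < pMax & entries$interactions >= minInteractions
  unique(normalizeSymbols(entries$gene[keep]))
}

#' Generic per-tool thresholder
#'
#' Phenotype-driven prioritizers often publish no numeric cut-off; their
#' lists are then consumed as already prioritized (pass-through default).
#' `topN` keeps the best-scoring N entries, `minScore` keeps entries with
#' `score >= minScore`.
#'
#' @param entries data.frame with columns `gene` and optionally `score`.
#' @param topN keep the top N by decreasing score (optional).
#' @param minScore inclusive score threshold (optional).
#' @return character vector of prioritized gene symbols.
#' @export
thresholdToolList <- function(entries, topN = NULL, minScore = NULL) {
  df <- data.frame(
    gene = normalizeSymbols(entries$gene),
    score = if (is.null(entries$score)) NA_real_ else
      as.numeric(entries$score),
    stringsAsFactors = FALSE)
  if (!is.null(minScore))
    df <- df[!is.na(df$score) & df$score >= minScore, , drop = FALSE]
  if (!is.null(topN)) {
    df <- df[order(-df$score), , drop = FALSE]
    df <- df[seq_len(min(topN, nrow(df))), , drop = FALSE]
  }
  unique(df$gene)
}

#' k-of-n consensus over per-tool gene sets
#'
#' Counts in how many tools each gene is prioritized and returns the nested
#' family of k-of-n sets. The result is invariant under tool order and list
#' order; `kOfN[[k + 1]]` is always a subset of `kOfN[[k]]`.
#'
#' @param toolSets named list of character vectors (one per tool).
#' @param minTools genes prioritized by at least this many tools form the
#'   `selected` set (default `length(toolSets) - 1`, i.e. "at least three of
#'   four" for four tools).
#' @return list with `perTool` (normalized input sets), `counts`
#'   (data.frame `gene`, `nTools`, `tools`), `kOfN` (list of symbol vectors
#'   indexed `"1" .. "n"`), `fullOverlap` (= `kOfN[[n]]`) and `selected`.
#' @examples
#' consensusGenes(list(a = c("G1", "G2"), b = c("G2", "G3")), minTools = 2)
#' @export
consensusGenes <- function(toolSets, minTools = max(1L,
                                                    length(toolSets) - 1L)) {
  n <- length(toolSets)
  if (n < 1L) abort("'toolSets' must contain at least one tool")
  if (minTools < 1L || minTools > n)
    abort("'minTools' must lie in 1..", n)
  if (is.null(names(toolSets)) || any(!nzchar(names(toolSets))))
    names(toolSets) <- paste0("tool", seq_len(n))
  sets <- lapply(toolSets, function(s) unique(normalizeSymbols(s)))
  genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(sets)))
  nTools <- rowSums(member)
  counts <- data.frame(
    gene = genes, nTools = as.integer(nTools),
    tools = apply(member, 1L, function(r)
      paste(colnames(member)[r], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL)
  counts <- counts[order(-counts$nTools, counts$gene), , drop = FALSE]
  rownames(counts) <- NULL
  kOfN <- lapply(seq_len(n), function(k) genes[nTools >= k])
  names(kOfN) <- as.character(seq_len(n))
  list(perTool = sets, counts = counts, kOfN = kOfN,
       fullOverlap = kOfN[[n]], selected = kOfN[[minTools]])
}

#' Merge source gene lists into a training set
#'
#' Case-normalized union of named source lists with per-source provenance,
#' e.g. for assembling a disease-gene training set from several curated
#' databases.
#'
#' @param sourceLists named list of character vectors.
#' @return list with `genes` (sorted unique symbols) and `provenance`
#'   (data.frame `gene`, `sources`).
#' @export
buildTrainingSet <- function(sourceLists) {
  if (length(sourceLists) == 0L)
    return(list(genes = character(),
                provenance = data.frame(gene = character(),
                                        sources = character())))
  if (is.null(names(sourceLists)))
    names(sourceLists) <- paste0("source", seq_along(sourceLists))
  sets <- lapply(sourceLists, function(s) unique(normalizeSymbols(s)))
  genes <- sort(unique(unlist(sets)))
  src <- vapply(genes, function(g)
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1L))],
          collapse = ","), character(1L))
  list(genes = genes,
       provenance = data.frame(gene = genes, sources = unname(src),
                               stringsAsFactors = FALSE))
}

#' Read per-tool gene lists
#'
#' One TSV per tool with header `gene_symbol [score] [secondary_score]`;
#' the tool name defaults to the file name without extension.
#'
#' @param files character vector of file paths, optionally named by tool.
#' @return named list of data.frames with columns `gene` and any scores.
#' @export
readToolGeneLists <- function(files) {
  nm <- names(files) %||% tools::file_path_sans_ext(basename(files))
  nm[!nzchar(nm)] <- tools::file_path_sans_ext(basename(files))[!nzchar(nm)]
  out <- lapply(files, function(f) {
    df <- readTsv(f, "gene_symbol")
    names(df)[names(df) == "gene_symbol"] <- "gene"
    df$gene <- normalizeSymbols(df$gene)
    df
  })
  names(out) <- nm
  out
}
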