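# shared constructors for tiny in-code fixtures

# GRanges of population records from region strings
popRecords <- function(regions, states, accession = NULL) {
  gr <- parseRegion(regions)
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    accession = accession %||% sprintf("essv%03d", seq_along(gr)),
    copyState = states)
  gr
}

# GRanges of curated regions with categories
curatedRegions <- function(regions, categories) {
  gr <- parseRegion(regions)
  GenomicRanges::mcols(gr)$category <- asCategory(categories)
  gr
}

# gene model GRanges built directly
geneModelOf <- function(chrom, start, end, symbol,
                        biotype = "protein_coding") {
  n <- length(symbol)
  gr <- parseRegion(sprintf("%s:%d-%d", rep_len(chrom, n), start, end))
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    symbol = symbol, biotype = rep_len(biotype, n))
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent per-base overlap oracle: positions are counted under the
# (start, end] reading that makes length equal end - start
bruteOverlap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  length(intersect(seq.int(s1 + 1, e1), seq.int(s2 + 1, e2)))
}

randomPairs <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chromA = sample(c("1", "2"), n, TRUE),
    chromB = sample(c("1", "2"), n, TRUE),
    startA = sample.int(5000, n, replace = TRUE),
    startB = sample.int(5000, n, replace = TRUE),
    lenA = sample.int(3000, n, replace = TRUE),
    lenB = sample.int(3000, n, replace = TRUE))
}
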