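## Interval data model and overlap arithmetic.
##
## Coordinates are kept exactly as clinical CNV tables print them: 1-based,
## with segment length defined as end - start. That convention reproduces
## every internally consistent printed Mb size; the one-base difference from
## an inclusive or half-open reading is far below display rounding and is
## fixed here by fiat. GRanges is the container; its width slot (end-start+1)
## is deliberately not used for lengths.

#' Accepted chromosome labels in canonical report order
#'
#' Autosomes 1-22 numerically, then X and Y.
#'
#' @return character vector of normalized chromosome labels.
#' @export
chromLevels <- function() c(as.character(1:22), "X", "Y")

#' Normalize chromosome labels
#'
#' Maps the dialects seen in CNV tables ("chr8", "Chr8", "8", "chrX", "x")
#' onto the canonical label set `1..22, X, Y`.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @examples
#' normalizeChrom(c("chr8", "Chr8", "8", "chrx")) # "8" "8" "8" "X"
#' @export
normalizeChrom <- function(chrom) {
  x <- toupper(sub("^[Cc][Hh][Rr]", "", trimws(as.character(chrom))))
  bad <- !(x %in% chromLevels())
  if (any(bad))
    abort("unknown chromosome label(s): ",
          paste(unique(chrom[bad]), collapse = ", "))
  x
}

newInterval <- function(chrom, start, end) {
  chrom <- normalizeChrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyNA(start) || anyNA(end) || any(start < 1))
    abort("interval start/end must be integers with start >= 1")
  bad <- which(end <= start)
  if (length(bad))
    abort(sprintf("zero- or negative-length interval: %s:%s-%s",
                  chrom[bad[1L]], format(start[bad[1L]], scientific = FALSE),
                  format(end[bad[1L]], scientific = FALSE)))
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = chromLevels()),
    ranges = IRanges::IRanges(start = start, end = end))
}

#' Parse printed genomic-region strings
#'
#' Parses the `Chr8:128,538,700-146,262,124` convention used in clinical CNV
#' tables: optional `chr`/`Chr` prefix, thousands commas, and either an ASCII
#' hyphen or an en dash between start and end.
#'
#' @param text character vector of region strings.
#' @return a [GenomicRanges::GRanges] with normalized seqnames. Coordinates
#'   are stored as printed (1-based); see [lengthBp()] for the length
#'   convention.
#' @examples
#' parseRegion("Chr8:128,538,700-146,262,124")
#' parseRegion("2:50203462-50232894")
#' @export
parseRegion <- function(text) {
  text <- as.character(text)
  stripped <- gsub(",", "", trimws(text))
  # – is the en dash used in print
  m <- regmatches(stripped,
                  regexec("^([^:]+):([0-9]+)[-–]([0-9]+)$", stripped))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    abort("malformed region string: '", text[which(bad)[1L]], "'")
  parts <- do.call(rbind, m)
  newInterval(parts[, 2L], parts[, 3L], parts[, 4L])
}

#' Format intervals back to region strings
#'
#' Inverse of [parseRegion()] on normalized intervals:
#' `formatRegion(parseRegion(x))` reprints `x` in the canonical dialect
#' (`Chr` prefix, thousands commas, ASCII hyphen).
#'
#' @param x a `GRanges`.
#' @param commas insert thousands separators (default `TRUE`).
#' @return character vector of region strings.
#' @export
formatRegion <- function(x, commas = TRUE) {
  fmt <- function(v) if (commas) formatC(v, format = "d", big.mark = ",")
  else formatC(v, format = "d")
  sprintf("Chr%s:%s-%s", as.character(GenomicRanges::seqnames(x)),
          fmt(GenomicRanges::start(x)), fmt(GenomicRanges::end(x)))
}

#' Segment length in base pairs
#'
#' `end - start` under the printed 1-based convention (not GRanges width).
#'
#' @param x a `GRanges`.
#' @return numeric vector of lengths in bp.
#' @export
lengthBp <- function(x) GenomicRanges::end(x) - GenomicRanges::start(x)

#' Segment length in megabases, display-rounded
#'
#' Converts [lengthBp()] to Mb and applies the tables' display rule: half-up
#' to one decimal for segments of at least 0.1 Mb, two decimals below that
#' (so a 29.4 kb deletion prints as 0.03 Mb, not 0.0).
#'
#' @param x a `GRanges`.
#' @return numeric vector of display sizes in Mb.
#' @examples
#' lengthMb(parseRegion("Chr8:128,538,700-146,262,124")) # 17.7
#' lengthMb(parseRegion("Chr2:50,203,462-50,232,894"))   # 0.03
#' @export
lengthMb <- function(x) {
  mb <- lengthBp(x) / 1e6
  ifelse(mb >= 0.1, roundHalfUp(mb, 1), roundHalfUp(mb, 2))
}

#' Pairwise overlap in base pairs
#'
#' Element-wise intersection length of two interval vectors (recycled if one
#' has length 1), under the same `end - start` length convention. Intervals
#' on different chromosomes, or disjoint ones, overlap by 0.
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return numeric vector of overlaps in bp.
#' @export
overlapBp <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  if (length(a) != length(b))
    abort("'a' and 'b' must have equal length (or length 1)")
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b))
  ifelse(same, pmax(0, ov), 0)
}

#' Reciprocal overlap fraction
#'
#' The standard CNV matching statistic:
#' `min(overlap/length(a), overlap/length(b))`. Symmetric in its arguments
#' and in `[0, 1]`; 1 only for identical intervals.
#'
#' @param a,b `GRanges` of equal length (or length 1).
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- parseRegion("1:100-1100"); b <- parseRegion("1:100-200")
#' reciprocalOverlap(a, b) # 0.1
#' @export
reciprocalOverlap <- function(a, b) {
  ov <- overlapBp(a, b)
  n <- max(length(a), length(b))
  la <- rep_len(lengthBp(a), n)
  lb <- rep_len(lengthBp(b), n)
  pmin(ov / la, ov / lb)
}

# plain-vector reciprocal overlap of one query against many subjects;
# the workhorse behind the population filter and region matchers (kept off
# the S4 containers because it runs in tight loops)
.ro1 <- function(chrom, start, end, sChrom, sStart, sEnd) {
  ov <- pmin(sEnd, end) - pmax(sStart, start)
  ov[sChrom != chrom | ov < 0] <- 0
  pmin(ov / (end - start), ov / (sEnd - sStart))
}

# Reciprocal overlap of one query against every subject; returns a numeric
# vector over subjects.
reciprocalOverlapMany <- function(query, subjects) {
  if (length(query) != 1L) abort("'query' must be a single interval")
  .ro1(as.character(GenomicRanges::seqnames(query)),
       GenomicRanges::start(query), GenomicRanges::end(query),
       as.character(GenomicRanges::seqnames(subjects)),
       GenomicRanges::start(subjects), GenomicRanges::end(subjects))
}
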