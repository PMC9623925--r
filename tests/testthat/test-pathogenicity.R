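test_that("mvpCategory reproduces every published (score, label) pair", {
  pairs <- list(c(0.862, "pathogenic"), c(0.840, "pathogenic"),
                c(0.854, "pathogenic"), c(0.527, "likely_pathogenic"),
                c(0.544, "likely_pathogenic"), c(0.282, "uncertain"),
                c(0.187, "uncertain"), c(0.154, "likely_benign"),
                c(0.141, "likely_benign"), c(0.123, "benign"))
  for (p in pairs)
    expect_equal(as.character(mvpCategory(as.numeric(p[1]))), p[2])
})

test_that("mvpCategory bins are left-closed and validate their inputs", {
  cuts <- c(0.14, 0.18, 0.50, 0.75)
  expect_equal(as.character(mvpCategory(cuts)),
               c("likely_benign", "uncertain", "likely_pathogenic",
                 "pathogenic"))
  expect_error(mvpCategory(1.2), "\\[0, 1\\]")
  expect_error(mvpCategory(-0.1), "\\[0, 1\\]")
  expect_error(mvpCategory(0.5, cutpoints = c(0.5, 0.4, 0.6, 0.7)),
               "ascending")
})

test_that("increasing MVP score never moves the category toward benign", {
  set.seed(1)
  scores <- sort(runif(400))
  sev <- c(benign = 1, likely_benign = 2, uncertain = 3,
           likely_pathogenic = 4, pathogenic = 5)
  ranks <- sev[as.character(mvpCategory(scores))]
  expect_true(all(diff(ranks) >= 0))
})

test_that("decipherVerdict picks the best-overlapping qualifying region", {
  cnv <- CnvCalls("p", "1", 1, 1001, "del")
  regions <- curatedRegions(c("1:1-801", "1:1-901"),
                            c("likely_pathogenic", "benign"))
  # overlaps 0.8 and 0.9: the better-overlapping benign region wins
  expect_equal(as.character(decipherVerdict(cnv, regions)), "benign")

  # exhaustive enumeration oracle for the same rule
  ro <- vapply(seq_along(regions), function(j)
    reciprocalOverlap(cnv, regions[j]), numeric(1))
  qual <- which(ro > 0.5)
  expect_equal(as.character(decipherVerdict(cnv, regions)),
               as.character(GenomicRanges::mcols(regions)$category[
                 qual[which.max(ro[qual])]]))

  # identity overlap inherits the region's category
  same <- curatedRegions("1:1-1,001", "pathogenic")
  expect_equal(as.character(decipherVerdict(cnv, same)), "pathogenic")
  # no qualifying region: not mentioned
  far <- curatedRegions("2:1-1,001", "pathogenic")
  expect_equal(as.character(decipherVerdict(cnv, far)), "not_mentioned")
})

test_that("decipherVerdict breaks exact overlap ties toward severity", {
  cnv <- CnvCalls("p", "1", 1, 1001, "del")
  tied <- curatedRegions(c("1:1-901", "1:101-1,001"),
                         c("uncertain", "likely_pathogenic"))
  expect_equal(as.character(decipherVerdict(cnv, tied)),
               "likely_pathogenic")
})

test_that("omimVerdict follows the disease > phenotype > absent order", {
  gm <- data.frame(gene = c("TBX1", "GENEX"),
                   association = c("disease", "phenotype"))
  expect_equal(as.character(omimVerdict(c("TBX1", "SNAP29"), gm)),
               "pathogenic")
  expect_equal(as.character(omimVerdict("GENEX", gm)), "likely_pathogenic")
  expect_equal(as.character(omimVerdict(c("tbx1"), gm)), "pathogenic")
  expect_equal(as.character(omimVerdict(character(), gm)), "not_mentioned")
  expect_equal(as.character(omimVerdict("UNRELATED", gm)), "not_mentioned")
})

test_that("consensusClassify is an any-of-three P/LP rule", {
  expect_true(consensusClassify("benign", "not_mentioned", "pathogenic"))
  expect_true(consensusClassify("likely_benign", "likely_pathogenic",
                                "not_mentioned"))
  expect_false(consensusClassify("benign", "not_mentioned",
                                 "not_mentioned"))
  expect_false(consensusClassify("uncertain", "likely_benign", "benign"))
  # vectorized over rows
  expect_equal(consensusClassify(c("pathogenic", "benign"),
                                 c("NM", "NM"), c("NM", "NM")),
               c(TRUE, FALSE))
})

test_that("consensus is monotone in each source under the severity order", {
  lv <- c("benign", "likely_benign", "uncertain", "likely_pathogenic",
          "pathogenic")
  for (a in lv) for (b in lv) {
    base <- consensusClassify(a, b, "not_mentioned")
    for (up in lv[seq(which(lv == a), 5)])
      expect_true(consensusClassify(up, b, "not_mentioned") >= base)
  }
})

test_that("classifyCnvs assembles verdicts from sources end to end", {
  calls <- CnvCalls(c("p1", "p2", "p3"), c("1", "2", "3"),
                    c(1e6, 1e6, 1e6), c(2e6, 2e6, 2e6),
                    c("del", "del", "dup"))
  regions <- curatedRegions("1:1,050,000-2,050,000", "pathogenic")
  gm <- geneModelOf("2", 1200000L, 1300000L, "DISG")
  omim <- data.frame(gene = "DISG", association = "disease")
  ann <- classifyCnvs(calls, mvpScore = c(0.05, 0.05, 0.9),
                      decipherRegions = regions, omimMap = omim,
                      geneModel = gm)
  mc <- GenomicRanges::mcols(ann)
  expect_equal(as.character(mc$decipherCategory),
               c("pathogenic", "not_mentioned", "not_mentioned"))
  expect_equal(as.character(mc$omimCategory),
               c("not_mentioned", "pathogenic", "not_mentioned"))
  expect_equal(as.character(mc$mvpCategory),
               c("benign", "benign", "pathogenic"))
  expect_equal(mc$consensusPlp, c(TRUE, TRUE, TRUE))
})

test_that("category labels in display spelling normalize cleanly", {
  expect_equal(as.character(asCategory(c("Likely pathogenic", "NM",
                                         "Benign", "likely benign"))),
               c("likely_pathogenic", "not_mentioned", "benign",
                 "likely_benign"))
  expect_error(asCategory("pathogenic-ish"), "unknown pathogenicity")
})
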