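test_that("flagGross excludes whole patients above the size threshold", {
  calls <- CnvCalls(
    c("case41", "case74", "case74", "ok1"),
    c("3", "2", "3", "7"),
    c(1e6, 1e6, 5e6, 2e6),
    c(1e6 + 34.8e6, 1e6 + 37.2e6, 5e6 + 3.6e6, 2e6 + 2.5e6),
    c("dup", "dup", "dup", "del"))
  fl <- flagGross(calls)
  expect_setequal(fl$sampleId, c("case41", "case74"))
  expect_true(all(fl$reason == "gross_aberration"))

  # all calls of a flagged patient drop, including the 3.6 Mb one
  rep <- filterCohort(calls, popdb = NULL)
  expect_equal(length(candidateCnvs(rep)), 1L)
  expect_equal(sampleId(candidateCnvs(rep)), "ok1")
  expect_setequal(
    GenomicRanges::mcols(excludedCnvs(rep))$reason, "patient_excluded")
})

test_that("aneuploidy flags take precedence and span detection works", {
  calls <- CnvCalls(c("tri21", "big"), c("21", "1"), c(1, 1e6),
                    c(48e6, 41e6), c("dup", "dup"),
                    aneuploidy = c(TRUE, FALSE))
  fl <- flagGross(calls)
  expect_equal(fl$reason[fl$sampleId == "tri21"], "aneuploidy")
  expect_equal(fl$reason[fl$sampleId == "big"], "gross_aberration")

  # span-based detection without an explicit flag
  calls2 <- CnvCalls("t19", "19", 1, 58e6, "dup")
  expect_equal(nrow(flagGross(calls2)), 1L)  # > 30 Mb, gross
  fl2 <- flagGross(calls2, chromLengths = chromLengthsDefault())
  expect_equal(fl2$reason, "aneuploidy")  # spans > 90% of chr19
})

test_that("isCommon applies strict thresholds on overlap and occurrences", {
  q <- CnvCalls("p1", "1", 10e6, 11e6, "del")
  match5 <- popRecords(rep("1:10,010,000-11,010,000", 5), rep("deletion", 5))
  match4 <- match5[1:4]
  none <- popRecords("2:10,000,000-11,000,000", "deletion")

  expect_true(isCommon(q, match5)$common)            # 5 matches > 4
  expect_false(isCommon(q, match4)$common)           # exactly 4: rare
  expect_false(isCommon(q, none)$common)             # 0 matches
  expect_equal(isCommon(q, match5)$nMatches, 5L)

  # brute-force oracle over a mixed constructed database
  popdb <- c(match5, none,
             popRecords("1:10,600,000-11,600,000", "deletion"),  # ro = 0.4
             popRecords("1:10,010,000-11,010,000", "duplication"))
  got <- isCommon(q, popdb)
  ro <- vapply(seq_along(popdb), function(j)
    reciprocalOverlap(q, popdb[j]), numeric(1))
  sameState <- GenomicRanges::mcols(popdb)$copyState %in%
    c("deletion", "both")
  expect_equal(got$nMatches, sum(ro > 0.5 & sameState))
  expect_true(got$common)

  # copy-state matching is configurable; 'both' matches either state
  expect_equal(isCommon(q, popdb, matchCopyState = FALSE)$nMatches,
               sum(ro > 0.5))
  both <- popRecords(rep("1:10,010,000-11,010,000", 5), rep("both", 5))
  expect_true(isCommon(q, both)$common)
})

test_that("exact reciprocal overlap of 0.5 does not count as a match", {
  q <- CnvCalls("p1", "1", 1e6, 2e6, "del")
  half <- popRecords(rep("1:1,500,000-2,500,000", 10), rep("deletion", 10))
  expect_equal(isCommon(q, half)$nMatches, 0L)
})

test_that("filterCohort partitions calls and reproduces planted labels", {
  sim <- simulateCohort(simulationConfig(seed = 31),
                        components = c("calls", "popdb"))
  rep <- filterCohort(sim$calls, sim$popdb, samples = sim$samples)

  expect_equal(rep@nPatients, 109L)
  expect_equal(yieldDenominator(rep), 104L)
  expect_setequal(excludedPatients(rep)$sampleId,
                  c(sim$truth$aneuploidyPatients, sim$truth$grossPatients))
  ids <- GenomicRanges::mcols(candidateCnvs(rep))$cnvId
  expect_setequal(ids, sim$truth$candidateCnvIds)
  expect_equal(length(candidateCnvs(rep)) + length(excludedCnvs(rep)),
               length(sim$calls))
  common <- GenomicRanges::mcols(excludedCnvs(rep))
  expect_setequal(
    common$cnvId[common$reason == "common_in_population"],
    sim$truth$commonCnvIds)
})

test_that("a cohort where every call is common yields no candidates", {
  calls <- CnvCalls(c("a", "b"), c("1", "2"), c(1e6, 5e6), c(2e6, 6e6),
                    c("del", "dup"))
  popdb <- c(popRecords(rep("1:1,010,000-2,010,000", 10),
                        rep("deletion", 10)),
             popRecords(rep("2:5,010,000-6,010,000", 10),
                        rep("duplication", 10)))
  rep <- filterCohort(calls, popdb)
  expect_equal(length(candidateCnvs(rep)), 0L)
  expect_equal(yieldDenominator(rep), 2L)
})

test_that("an empty cohort gives an empty report with denominator 0", {
  rep <- filterCohort(CnvCalls(character(), character(), numeric(),
                               numeric(), character()), popdb = NULL)
  expect_equal(yieldDenominator(rep), 0L)
  expect_equal(length(candidateCnvs(rep)), 0L)
})

test_that("filtering is idempotent and monotone in both thresholds", {
  sim <- simulateCohort(simulationConfig(seed = 57),
                        components = c("calls", "popdb"))
  rep <- filterCohort(sim$calls, sim$popdb, samples = sim$samples)
  again <- filterCohort(candidateCnvs(rep), sim$popdb)
  expect_equal(length(candidateCnvs(again)), length(candidateCnvs(rep)))
  expect_equal(nrow(excludedPatients(again)), 0L)

  nCand <- function(maxOcc, minRec)
    length(candidateCnvs(filterCohort(sim$calls, sim$popdb,
                                      samples = sim$samples,
                                      maxOccurrences = maxOcc,
                                      minReciprocal = minRec)))
  byOcc <- vapply(c(0, 2, 4, 6, 10), nCand, numeric(1), minRec = 0.5)
  expect_true(all(diff(byOcc) >= 0))
  byRec <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r) nCand(4, r),
                  numeric(1))
  expect_true(all(diff(byRec) >= 0))
})

test_that("the partition invariant holds on randomized cohorts", {
  for (seed in c(101, 202, 303)) {
    sim <- simulateCohort(simulationConfig(seed = seed),
                          components = c("calls", "popdb"))
    rep <- filterCohort(sim$calls, sim$popdb, samples = sim$samples)
    expect_equal(length(candidateCnvs(rep)) + length(excludedCnvs(rep)),
                 length(sim$calls))
    expect_equal(yieldDenominator(rep),
                 rep@nPatients - nrow(excludedPatients(rep)))
    both <- intersect(GenomicRanges::mcols(candidateCnvs(rep))$cnvId,
                      GenomicRanges::mcols(excludedCnvs(rep))$cnvId)
    expect_length(both, 0)
  }
})
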