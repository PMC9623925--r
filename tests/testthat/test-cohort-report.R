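test_that("chdCategory applies the documented precedence", {
  expect_equal(as.character(chdCategory(list("VSD"))), "A")
  expect_equal(as.character(chdCategory(list(c("VSD", "MR")))), "C")
  expect_equal(as.character(chdCategory(list(c("TOF", "RAA")))), "F")
  expect_equal(as.character(chdCategory(list("TOF"))), "E")
  expect_equal(as.character(chdCategory(list(c("DORV", "TGA", "VSD")))),
               "F")
  expect_equal(as.character(chdCategory(list("CoA"))), "D")
  expect_equal(as.character(chdCategory(list("MR"))), "B")
  expect_equal(as.character(chdCategory(list("PDA"))), "H")
  expect_equal(as.character(
    chdCategory(list(c("heterotaxy syndrome", "TOF", "VSD")))), "G")
  expect_error(chdCategory(list(character())), "non-empty")
  expect_warning(chdCategory(list("unheard-of defect")), "unmapped")
})

test_that("diagnosticYield and overallImbalance reproduce the arithmetic", {
  samples <- sprintf("p%03d", 1:109)
  excluded <- samples[1:5]
  carriers <- samples[6:29]          # 24 P/LP carriers
  rawCarriers <- samples[6:42]       # 37 patients with any call
  y <- diagnosticYield(samples, excluded, carriers)
  expect_equal(y$numerator, 24L)
  expect_equal(y$denominator, 104L)
  expect_equal(y$pct, 23.1)
  imb <- overallImbalance(samples, excluded, rawCarriers)
  expect_equal(imb$numerator, 42L)
  expect_equal(imb$pct, 38.5)

  none <- diagnosticYield(sprintf("q%d", 1:10), character(), character())
  expect_equal(none$pct, 0.0)
  empty <- diagnosticYield(character(), character(), character())
  expect_true(is.na(empty$pct))
  # excluded carriers never count toward the numerator
  y2 <- diagnosticYield(samples, samples[1:5], samples[c(1, 6)])
  expect_equal(y2$numerator, 1L)
})

test_that("summarizeCohort reproduces the case-study marginals", {
  cohort <- caseCohort()
  expect_equal(nrow(cohort), 109L)
  sc <- summarizeCohort(cohort)
  expect_equal(sc$counts["A", "Total"], 72)
  expect_equal(sc$totalPct[["A"]], 66.1)
  expect_equal(sc$columnPct[["Neurodevelopmental"]], 33.9)
  expect_equal(sc$totalPct[["F"]], 10.1)
  expect_equal(sc$totalPct[["D"]], 7.3)
  # cross-tab invariants
  expect_equal(sum(sc$counts[, "Total"]), 109)
  expect_equal(unname(rowSums(sc$counts[, -1])),
               unname(sc$counts[, "Total"]))
  # row percentages use row totals (class A: 30/72)
  expect_equal(sc$rowPct["A", "Neurodevelopmental"], 41.7)
})

test_that("a single-patient cohort fills its single cell at 100%", {
  cohort <- data.frame(sample_id = "only", sex = NA, age = NA,
                       cardiac_terms = I(list("VSD")),
                       extracardiac_primary = "Craniofacial")
  sc <- summarizeCohort(cohort)
  expect_equal(sc$counts["A", "Craniofacial"], 1)
  expect_equal(sc$rowPct["A", "Craniofacial"], 100.0)
  expect_equal(sc$totalPct[["A"]], 100.0)
})

test_that("cnvDistributions bins chromosomes and sizes as documented", {
  calls <- CnvCalls(c("a", "b", "c"), c("22", "22", "8"),
                    c(1e6, 2e6, 1e6),
                    c(1e6 + 2.5e6, 2e6 + 17.7e6, 1e6 + 0.03e6),
                    c("del", "del", "dup"))
  d <- cnvDistributions(calls)
  expect_equal(unname(d$chromCounts[c("8", "22")]), c(1L, 2L))
  expect_equal(names(d$chromCounts), c("8", "22"))  # canonical order
  h <- setNames(d$sizeHist$count, d$sizeHist$bin)
  expect_equal(unname(h[c("[0,1)", "[1,5)", "[10,20)")]), c(1L, 1L, 1L))
  expect_equal(sum(d$sizeHist$count), 3L)

  empty <- cnvDistributions(
    CnvCalls(character(), character(), numeric(), numeric(), character()))
  expect_equal(sum(empty$sizeHist$count), 0L)
  expect_length(empty$chromCounts, 0)

  big <- CnvCalls("x", "1", 1e6, 46e6, "dup")
  expect_warning(db <- cnvDistributions(big), "overflow")
  expect_equal(setNames(db$sizeHist$count, db$sizeHist$bin)[[">=40"]], 1L)
})

test_that("cohort tables read from TSV with ;-separated cardiac terms", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tage\tcardiac_terms\textracardiac_primary",
               "p1\tM\t0.5\tVSD;MR\tNeurodevelopmental",
               "p2\tF\t2\tTOF\tCraniofacial"), f)
  tab <- readCohortTable(f)
  expect_equal(tab$cardiac_terms[[1]], c("VSD", "MR"))
  expect_equal(as.character(chdCategory(tab$cardiac_terms)), c("C", "E"))
})
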