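test_that("classifyPatient separates syndromic, isolated and no-CHD", {
  v <- cardiacVocabulary()
  expect_equal(as.character(classifyPatient(
    c("VSD", "Intellectual disability"), v)), "syndromic_chd")
  expect_equal(as.character(classifyPatient("Tetralogy of Fallot", v)),
               "isolated_chd")
  expect_equal(as.character(classifyPatient("Micrognathia", v)), "no_chd")
  expect_equal(as.character(classifyPatient(character(), v)), "no_chd")
  # case-folding
  expect_equal(as.character(classifyPatient("tetralogy of fallot", v)),
               "isolated_chd")
  expect_error(classifyPatient("VSD", character()), "non-empty")
})

test_that("regionSpectrum counts planted groups and formats percentages", {
  region <- CnvCalls("idx", "5", 1e6, 3e6, "del")
  mk <- function(id, terms, state = "deletion", chrom = "5",
                 start = 1.05e6, end = 3.05e6)
    data.frame(patient_id = id, chrom = chrom, start = start, end = end,
               copy_state = state, terms = I(list(terms)),
               stringsAsFactors = FALSE)
  patients <- rbind(
    mk("s1", c("VSD", "Hypotonia")),
    mk("s2", c("Tetralogy of Fallot", "Micrognathia")),
    mk("s3", "ASD"),
    mk("s4", "Low-set ears"),
    mk("s5", c("VSD", "Hypotonia"), state = "duplication"),  # wrong state
    mk("s6", c("VSD", "Hypotonia"), chrom = "6"))            # wrong chrom
  sp <- regionSpectrum(region, patients)
  expect_equal(sp$nTotal, 4)
  expect_equal(sp$nSyndromic, 2)
  expect_equal(sp$nIsolated, 1)
  expect_equal(sp$pctSyndromic, 50.0)
  expect_equal(sp$pctIsolated, 25.0)
  expect_equal(sp$topExtracardiac$term, c("hypotonia", "micrognathia"))
  expect_equal(sp$topCardiac$term, c("tetralogy of fallot", "vsd"))

  # copy-state matching is configurable
  sp2 <- regionSpectrum(region, patients, matchCopyState = FALSE)
  expect_equal(sp2$nTotal, 5)
})

test_that("zero matched patients give undefined percentages, not zero", {
  region <- CnvCalls("idx", "21", 1e6, 3e6, "del")
  patients <- data.frame(patient_id = "s1", chrom = "5", start = 1e6,
                         end = 3e6, copy_state = "deletion",
                         terms = I(list("VSD")), stringsAsFactors = FALSE)
  sp <- regionSpectrum(region, patients)
  expect_equal(sp$nTotal, 0)
  expect_true(is.na(sp$pctSyndromic))
  expect_true(is.na(sp$pctIsolated))
  expect_equal(nrow(sp$topCardiac), 0)
})

test_that("top-k tallies are deterministic under input permutation", {
  region <- CnvCalls("idx", "5", 1e6, 3e6, "del")
  terms <- list(c("VSD", "Hypotonia", "Micrognathia"),
                c("ASD", "Hypotonia"), c("VSD", "Cleft palate"),
                c("TOF", "Micrognathia"), c("VSD", "Hypertelorism"),
                c("ASD", "Low-set ears"), c("PDA", "Microcephaly"))
  patients <- data.frame(
    patient_id = sprintf("s%d", seq_along(terms)), chrom = "5",
    start = 1.01e6, end = 3.01e6, copy_state = "deletion",
    terms = I(terms), stringsAsFactors = FALSE)
  sp <- regionSpectrum(region, patients)
  set.seed(3)
  for (i in 1:5) {
    perm <- patients[sample(nrow(patients)), , drop = FALSE]
    sp2 <- regionSpectrum(region, perm)
    expect_identical(sp2$topCardiac, sp$topCardiac)
    expect_identical(sp2$topExtracardiac, sp$topExtracardiac)
  }
  # ties break lexicographically and k truncates
  expect_true(all(diff(sp$topCardiac$count) <= 0))
  expect_lte(nrow(sp$topExtracardiac), 5)
})

test_that("percent sum stays within rounding slack of 100", {
  sim <- simulateCohort(simulationConfig(seed = 21))
  sp <- regionSpectrum(sim$spectrumRegion, sim$patients)
  expect_lte(sp$pctSyndromic + sp$pctIsolated, 100 + 0.1)
})

test_that("differentialGenes returns sorted set differences", {
  d <- differentialGenes("STS", character())
  expect_equal(d$isolatedOnly, "STS")
  expect_length(d$syndromicOnly, 0)
  same <- differentialGenes(c("A", "B"), c("b", "a"))
  expect_length(same$isolatedOnly, 0)
  expect_length(same$syndromicOnly, 0)
  set.seed(8)
  for (i in 1:10) {
    a <- sample(sprintf("G%02d", 1:40), 15)
    b <- sample(sprintf("G%02d", 1:40), 15)
    got <- differentialGenes(a, b)
    expect_equal(got$isolatedOnly, sort(a[!a %in% b]))
    expect_equal(got$syndromicOnly, sort(b[!b %in% a]))
  }
})

test_that("spectrumTable summarizes several regions at once", {
  sim <- simulateCohort(simulationConfig(
    seed = 4, spectrumTotal = 60L, spectrumSyndromic = 20L,
    spectrumIsolated = 5L))
  plp <- sim$calls[GenomicRanges::mcols(sim$calls)$class == "plp"]
  tab <- spectrumTable(plp[1:3], sim$patients)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$nTotal[1], 60)
  expect_equal(tab$nSyndromic[1], 20)
  # other regions are disjoint from the spectrum region by construction
  expect_equal(tab$nTotal[2:3], c(0, 0))
})
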