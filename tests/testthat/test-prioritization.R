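test_that("thresholdToppGene applies strict p and inclusive interactions", {
  df <- data.frame(gene = c("a", "b", "c", "d"),
                   p = c(0.04, 0.05, 0.001, 0.04),
                   interactions = c(20, 100, 19, 200))
  got <- thresholdToppGene(df)
  expect_setequal(got, c("A", "D"))  # b fails p (strict), c fails count

  withMiss <- rbind(df, data.frame(gene = "e", p = NA,
                                   interactions = 50))
  expect_warning(got2 <- thresholdToppGene(withMiss), "missing")
  expect_setequal(got2, c("A", "D"))
})

test_that("thresholdToppGene matches a row-by-row oracle", {
  set.seed(13)
  df <- data.frame(gene = sprintf("g%03d", 1:100),
                   p = runif(100), interactions = sample(0:60, 100, TRUE))
  got <- thresholdToppGene(df, pMax = 0.3, minInteractions = 25)
  oracle <- toupper(df$gene[vapply(seq_len(100), function(i)
    df$p[i] < 0.3 && df$interactions[i] >= 25, logical(1))])
  expect_setequal(got, oracle)
})

test_that("consensusGenes handles degenerate and planted structures", {
  disjoint <- list(a = c("G1", "G2"), b = c("G3"), c = c("G4"),
                   d = c("G5", "G6"))
  cg <- consensusGenes(disjoint, minTools = 2)
  expect_length(cg$kOfN[["2"]], 0)
  expect_length(cg$fullOverlap, 0)

  same <- replicate(4, sprintf("G%02d", 1:7), simplify = FALSE)
  names(same) <- letters[1:4]
  expect_length(consensusGenes(same)$fullOverlap, 7)

  # planted: 16 genes in all four sets, 30 in exactly three, rest in <= 2
  set.seed(5)
  g <- sprintf("PG%03d", 1:120)
  full <- g[1:16]; three <- g[17:46]; rest <- g[47:120]
  sets <- replicate(4, character(), simplify = FALSE)
  names(sets) <- paste0("t", 1:4)
  for (x in full) for (t in 1:4) sets[[t]] <- c(sets[[t]], x)
  for (x in three) {
    keep <- sample(4, 3)
    for (t in keep) sets[[t]] <- c(sets[[t]], x)
  }
  for (x in rest) {
    k <- sample(0:2, 1)
    if (k > 0) for (t in sample(4, k)) sets[[t]] <- c(sets[[t]], x)
  }
  cg <- consensusGenes(sets, minTools = 3)
  expect_setequal(cg$kOfN[["4"]], full)
  expect_length(cg$kOfN[["3"]], 46)
  expect_setequal(cg$selected, c(full, three))
  # brute-force membership count oracle
  counts <- vapply(g, function(x)
    sum(vapply(sets, function(s) x %in% s, logical(1))), numeric(1))
  for (k in 1:4)
    expect_setequal(cg$kOfN[[as.character(k)]], g[counts >= k])
})

test_that("k-of-n sets nest and are invariant under permutation", {
  set.seed(99)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i)
      sample(sprintf("G%03d", 1:60), sample(10:40, 1)))
    names(sets) <- paste0("t", 1:4)
    cg <- consensusGenes(sets, minTools = 3)
    for (k in 1:3)
      expect_true(all(cg$kOfN[[as.character(k + 1)]] %in%
                        cg$kOfN[[as.character(k)]]))
    perm <- sample(4)
    shuffled <- lapply(sets[perm], sample)
    cg2 <- consensusGenes(shuffled, minTools = 3)
    expect_setequal(cg$selected, cg2$selected)
    expect_setequal(cg$fullOverlap, cg2$fullOverlap)
  }
})

test_that("buildTrainingSet unions with provenance", {
  ts <- buildTrainingSet(list(rddc = c("A", "B"), pheno = c("b", "C")))
  expect_equal(ts$genes, c("A", "B", "C"))
  expect_equal(ts$provenance$sources[ts$provenance$gene == "B"],
               "rddc,pheno")
  expect_length(buildTrainingSet(list())$genes, 0)

  # inclusion-exclusion on three synthetic lists with known overlaps
  l1 <- sprintf("G%02d", 1:30)
  l2 <- sprintf("G%02d", 21:50)
  l3 <- sprintf("G%02d", 46:60)
  got <- buildTrainingSet(list(a = l1, b = l2, c = l3))
  expect_length(got$genes, 30 + 30 + 15 - 10 - 5 - 0 + 0)
})

test_that("generic thresholder defaults to pass-through", {
  df <- data.frame(gene = c("x", "y", "z"), score = c(3, 1, 2))
  expect_setequal(thresholdToolList(df), c("X", "Y", "Z"))
  expect_equal(thresholdToolList(df, topN = 2), c("X", "Z"))
  expect_setequal(thresholdToolList(df, minScore = 2), c("X", "Z"))
})

test_that("simulated tool lists recover their planted overlap structure", {
  sim <- simulateCohort(simulationConfig(seed = 77),
                        components = c("calls", "annotations", "genes",
                                       "tools"))
  sets <- lapply(sim$toolLists, function(tl) {
    if (all(c("p", "interactions") %in% names(tl))) thresholdToppGene(tl)
    else thresholdToolList(tl)
  })
  expect_identical(lapply(sets, sort), sim$truth$toolSets)
  cg <- consensusGenes(sets, minTools = 3)
  expect_setequal(cg$fullOverlap, sim$truth$fullOverlapGenes)
  expect_setequal(cg$kOfN[["3"]],
                  union(sim$truth$fullOverlapGenes,
                        sim$truth$threeToolGenes))
})
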