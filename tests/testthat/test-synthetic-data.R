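test_that("config validation rejects impossible designs", {
  expect_error(syntheticConfig(sequencingDepth = 0), "sequencingDepth")
  expect_error(syntheticConfig(nOtus = 10, moduleSizes = c(20)), "larger")
  expect_error(syntheticConfig(nOtus = 30, moduleSizes = c(20, 20)),
               "sum to at most")
  expect_error(syntheticConfig(loadingStrength = c(0.5, 1.5)),
               "loadingStrength")
  expect_error(syntheticConfig(envLink = list("1" = list(
    variable = "XX", sign = 1))), "envLink")
})

test_that("counts are reproducible and column sums equal the depth", {
  cfg <- syntheticConfig(nOtus = 60, moduleSizes = c(10, 10),
                         sequencingDepth = 5000, seed = 42)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_true(all(colSums(SummarizedExperiment::assay(a)) == 5000))
  # a different seed changes the data
  c2 <- simulateDataset(syntheticConfig(nOtus = 60,
                                        moduleSizes = c(10, 10),
                                        sequencingDepth = 5000, seed = 43))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c2)))
})

test_that("per-kingdom blocks each close at the sequencing depth", {
  cfg <- syntheticConfig(nOtus = 80, moduleSizes = c(15, 15),
                         sequencingDepth = 4000, eukFraction = 0.3,
                         seed = 5)
  tab <- simulateDataset(cfg)
  kd <- taxonomy(tab)$kingdom
  expect_setequal(unique(kd), c("bacterioplankton", "microeukaryote"))
  v <- SummarizedExperiment::assay(tab)
  for (k in unique(kd))
    expect_true(all(colSums(v[kd == k, , drop = FALSE]) == 4000))
})

test_that("truth annotations cover all OTUs and envLink ties factor to env", {
  cfg <- syntheticConfig(nOtus = 50, moduleSizes = c(10, 10), seed = 9)
  tab <- simulateDataset(cfg)
  tm <- truthModules(tab)
  expect_length(tm, 50)
  expect_setequal(unique(tm), c("M1", "M2", "background"))
  expect_equal(sum(tm == "M1"), 10)
  # module 1 is TN-linked by default: the planted factor IS the TN profile
  fac <- S4Vectors::metadata(tab)$truth_factors
  for (z in c("zoneA", "zoneB")) {
    tn <- SummarizedExperiment::colData(tab)[rownames(fac[[z]]), "TN"]
    expect_equal(cor(fac[[z]][, "M1"], tn, method = "spearman"), 1)
  }
})

test_that("zero loading leaves planted modules uncorrelated and the
           thresholded network empty", {
  cfg <- smallConfig(3, loading = c(0, 0))
  tab <- simulateDataset(cfg)
  rel <- toRelative(prevalenceFilter(tab, "zoneA", 8))
  scr <- spearmanScreen(rel)
  tm <- truthModules(tab)
  m1 <- intersect(names(tm)[tm == "M1"], rownames(rel))
  R <- scr@R[m1, m1]
  # under independence at n = 10 the null |rho| already averages ~0.26,
  # so test that correlations are centred on zero and not above the null
  # magnitude
  expect_lt(abs(mean(R[upper.tri(R)], na.rm = TRUE)), 0.1)
  expect_lt(mean(abs(R[upper.tri(R)]), na.rm = TRUE), 0.32)
  edges <- sum(!is.na(scr@R) & abs(scr@R) >= 0.9 & scr@P < 0.01 &
                 scr@Q < 0.05, na.rm = TRUE) / 2
  expect_lte(edges, 5)  # at most the false-positive expectation
})

test_that("noise-free positive-loading modules have rank-identical
           profiles", {
  cfg <- syntheticConfig(nOtus = 40, moduleSizes = c(10, 10),
                         loadingStrength = c(0.95, 0.95), noiseSd = 0,
                         negFraction = 0, sequencingDepth = 200000,
                         seed = 2)
  tab <- simulateDataset(cfg)
  rel <- toRelative(tab[, zones(tab) == "zoneA"])
  tm <- truthModules(tab)
  m1 <- names(tm)[tm == "M1"]
  R <- spearmanScreen(rel)@R[m1, m1]
  expect_gt(mean(R[upper.tri(R)]), 0.98)
})

test_that("within-module correlation increases with loading strength", {
  meanAbsRho <- function(loading, seed) {
    cfg <- syntheticConfig(nOtus = 60, moduleSizes = c(15, 15),
                           loadingStrength = c(loading, loading),
                           seed = seed)
    tab <- simulateDataset(cfg)
    rel <- toRelative(tab[, zones(tab) == "zoneA"])
    tm <- truthModules(tab)
    m1 <- names(tm)[tm == "M1"]
    R <- spearmanScreen(rel)@R[m1, m1]
    mean(abs(R[upper.tri(R)]), na.rm = TRUE)
  }
  lows <- vapply(1:3, function(s) meanAbsRho(0.2, s), 0)
  highs <- vapply(1:3, function(s) meanAbsRho(0.9, s), 0)
  expect_gt(mean(highs), mean(lows))
  expect_gt(mean(highs), 0.7)
})

test_that("the strong-loading zone yields the larger network", {
  wins <- 0L
  for (s in 1:8) {
    tab <- simulateTwoZoneDataset(smallConfig(100 + s))
    eA <- nrow(edgeTable(pipelineNetwork(tab, "zoneA")$net))
    eB <- nrow(edgeTable(pipelineNetwork(tab, "zoneB")$net))
    if (eB > eA) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
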