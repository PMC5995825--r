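relTable <- function(values) {
  sweep <- apply(values, 2, function(x) x / sum(x))
  dimnames(sweep) <- dimnames(values)
  AbundanceTable(sweep, mode = "relative")
}

test_that("screen matches hand-computed rank correlations", {
  v <- rbind(a = c(1, 2, 3, 4, 5),
             b = c(2, 4, 6, 8, 10),
             c = c(5, 4, 3, 2, 1))
  colnames(v) <- paste0("S", 1:5)
  scr <- spearmanScreen(relTable(v))
  expect_equal(scr@R["a", "b"], 1)
  expect_equal(scr@R["a", "c"], -1)
  # the rank-difference formula on x=(1,2,3), y=(3,1,2):
  # rho = 1 - 6*6/(3*8) = -0.5 (normalization cancels on ranks)
  v3 <- rbind(x = c(1, 2, 3), y = c(3, 1, 2), z = c(2, 2, 2.5))
  colnames(v3) <- paste0("S", 1:3)
  expect_equal(bruteSpearman(v3)["x", "y"], -0.5)
})

test_that("constant OTU profiles yield NA correlation and never edges", {
  a <- c(0.10, 0.20, 0.30, 0.25, 0.15)
  v <- rbind(a = a, k = rep(0.2, 5), b = 0.8 - a)
  colnames(v) <- paste0("S", 1:5)
  tab <- AbundanceTable(v, mode = "relative")
  scr <- spearmanScreen(tab)
  expect_true(is.na(scr@R["k", "a"]))
  expect_equal(scr@P["k", "a"], 1)
  expect_true(is.na(scr@Q["k", "a"]))
  net <- buildNetwork(scr, tab, rMin = 0, pMax = 1.1, qMax = 1.1)
  expect_false("k" %in% rownames(nodeTable(net)))
})

test_that("screen agrees with an independent brute-force oracle and with
           cor.test p-values", {
  set.seed(31)
  v <- matrix(rpois(80, 30), nrow = 8,
              dimnames = list(paste0("o", 1:8), paste0("S", 1:10)))
  v[2, ] <- v[1, ] + rpois(10, 2)        # induce ties across rows
  tab <- relTable(v)
  scr <- spearmanScreen(tab)
  oracle <- bruteSpearman(SummarizedExperiment::assay(tab))
  expect_equal(unname(scr@R), unname(oracle), tolerance = 1e-12)
  # p-values match the t-approximation used by cor.test
  rel <- SummarizedExperiment::assay(tab)
  for (pair in list(c(1, 3), c(2, 7))) {
    ct <- suppressWarnings(
      cor.test(rel[pair[1], ], rel[pair[2], ], method = "spearman",
               exact = FALSE))
    expect_equal(scr@P[pair[1], pair[2]], unname(ct$p.value),
                 tolerance = 1e-9)
  }
})

test_that("edge set is invariant under sample permutation", {
  set.seed(8)
  tab <- simulateDataset(smallConfig(55))
  rel <- toRelative(prevalenceFilter(tab, "zoneA", 8))
  net1 <- buildNetwork(spearmanScreen(rel), rel)
  perm <- sample(ncol(rel))
  rel2 <- rel[, perm]
  net2 <- buildNetwork(spearmanScreen(rel2), rel2)
  expect_equal(edgeTable(net1)[, c("otu_a", "otu_b", "rho")],
               edgeTable(net2)[, c("otu_a", "otu_b", "rho")])
})

test_that("q-values: ties, uniform-null pi0, and BH domination", {
  q <- storeyQvalues(rep(0.3, 5))
  expect_true(all(q == q[1]))
  set.seed(77)
  p <- runif(10000)
  qs <- storeyQvalues(p)
  expect_gte(attr(qs, "pi0"), 0.9)
  expect_lte(attr(qs, "pi0"), 1.0)
  # pi0 <= 1 implies q <= BH everywhere
  expect_true(all(qs <= p.adjust(p, "BH") + 1e-12))
  # monotone non-decreasing in p
  ord <- order(p)
  expect_true(all(diff(qs[ord]) >= -1e-12))
  expect_identical(storeyQvalues(numeric(0)), numeric(0))
})

test_that("edges require all three thresholds simultaneously", {
  ids <- paste0("o", 1:4)
  mkScreen <- function(rho, p, q) {
    R <- P <- Q <- matrix(NA_real_, 4, 4, dimnames = list(ids, ids))
    diag(R) <- 1
    R[1, 2] <- R[2, 1] <- rho
    P[1, 2] <- P[2, 1] <- p
    Q[1, 2] <- Q[2, 1] <- q
    # fill remaining pairs as clearly non-edges
    for (i in 1:3) for (j in (i + 1):4) if (!(i == 1 && j == 2)) {
      R[i, j] <- R[j, i] <- 0.1
      P[i, j] <- P[j, i] <- 0.9
      Q[i, j] <- Q[j, i] <- 0.9
    }
    new("CorrelationScreen", R = R, P = P, Q = Q, nSamples = 10L,
        qMethod = "storey")
  }
  vals <- matrix(1 / 4, 4, 6, dimnames = list(ids, paste0("S", 1:6)))
  tab <- AbundanceTable(vals, mode = "relative")

  kept <- buildNetwork(mkScreen(0.95, 0.001, 0.01), tab)
  expect_equal(nrow(edgeTable(kept)), 1)
  expect_identical(edgeTable(kept)$sign, "positive")

  neg <- buildNetwork(mkScreen(-0.92, 0.005, 0.04), tab)
  expect_equal(nrow(edgeTable(neg)), 1)
  expect_identical(edgeTable(neg)$sign, "negative")

  expect_equal(nrow(edgeTable(
    buildNetwork(mkScreen(0.95, 0.02, 0.04), tab))), 0)  # p fails
  expect_equal(nrow(edgeTable(
    buildNetwork(mkScreen(0.95, 0.001, 0.06), tab))), 0) # q fails
  expect_equal(nrow(edgeTable(
    buildNetwork(mkScreen(0.85, 0.001, 0.01), tab))), 0) # rho fails
})

test_that("raising the correlation threshold never adds edges", {
  tab <- simulateDataset(smallConfig(66))
  rel <- toRelative(prevalenceFilter(tab, "zoneB", 8))
  scr <- spearmanScreen(rel)
  loose <- edgeTable(buildNetwork(scr, rel, rMin = 0.85))
  tight <- edgeTable(buildNetwork(scr, rel, rMin = 0.95))
  keyL <- paste(loose$otu_a, loose$otu_b)
  keyT <- paste(tight$otu_a, tight$otu_b)
  expect_true(all(keyT %in% keyL))
  expect_lte(nrow(tight), nrow(loose))
})
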