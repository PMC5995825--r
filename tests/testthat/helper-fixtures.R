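# Fixture builders shared across test files. All data are generated in
# code; no fixture files on disk.

# Small counts table: 5 OTUs x 6 samples over two zones, with hand-set
# presence patterns.
toyCounts <- function() {
  m <- matrix(c(
    10, 20, 30, 40, 50, 60,    # everywhere
     0,  5,  5,  5,  5,  5,    # absent in sample 1
     0,  0,  0,  0,  0,  0,    # absent everywhere
     3,  0,  4,  0,  6,  0,    # patchy
     1,  1,  1,  1,  1,  1),   # constant
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("Otu", 1:5), paste0("S", 1:6)))
  m
}

toyTable <- function(zone = rep(c("A", "B"), each = 3)) {
  AbundanceTable(
    toyCounts(),
    taxonomy = data.frame(
      kingdom = "bacterioplankton",
      phylum = c("Actinobacteria", "Cyanobacteria", "Actinobacteria",
                 "Proteobacteria", "Proteobacteria"),
      class = c("unclassified", "unclassified", "unclassified",
                "Alphaproteobacteria", "Betaproteobacteria"),
      row.names = paste0("Otu", 1:5)),
    sampleData = data.frame(zone = zone, TN = c(1, 2, 3, 4, 5, 6),
                            row.names = paste0("S", 1:6)))
}

# 6-node two-phylum fixture: positive triangle within phylum A, phylum B
# isolated. The node universe (all 6) matters for the combinatorial O/R
# oracle, so isolated vertices are kept.
twoPhylumTriangle <- function() {
  g <- igraph::make_graph(~ n1 - n2, n2 - n3, n1 - n3) +
    igraph::vertices("n4", "n5", "n6")
  CoNetwork(g, phylum = setNames(c("A", "A", "A", "B", "B", "B"),
                                 paste0("n", 1:6)),
            dropIsolated = FALSE)
}

# Named complete graph.
namedCliqueGraph <- function(n, prefix = "v") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

# Small synthetic configuration used by several module tests.
smallConfig <- function(seed, loading = c(0.95, 0.95), ...) {
  syntheticConfig(nOtus = 120, moduleSizes = rep(20, 4),
                  loadingStrength = loading, seed = seed, ...)
}

# One-zone pipeline: filter -> relative -> screen -> network.
pipelineNetwork <- function(tab, zone = "zoneA", minPrevalence = 8) {
  rel <- toRelative(prevalenceFilter(tab, zone, minPrevalence))
  list(rel = rel, net = buildNetwork(spearmanScreen(rel), rel))
}

# Independent Spearman oracle: explicit average ranks, textbook
# product-moment formula evaluated pairwise in loops.
bruteSpearman <- function(values) {
  n <- nrow(values)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rx <- rank(values[i, ]); ry <- rank(values[j, ])
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    denom <- sqrt(sum(dx^2) * sum(dy^2))
    out[i, j] <- out[j, i] <- if (denom == 0) NA_real_
                              else sum(dx * dy) / denom
  }
  dimnames(out) <- list(rownames(values), rownames(values))
  out
}
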