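#' Detect modules by fast greedy modularity optimization
#'
#' Partitions the network into modules by greedy agglomerative maximization
#' of Newman's modularity Q on the unweighted, sign-blind graph; the
#' partition with maximal Q along the merge path is returned. The algorithm
#' is deterministic for a given graph.
#'
#' @param x a [CoNetwork-class] with at least one node.
#' @return A [ModulePartition-class].
#' @export
setMethod("detectModules", "CoNetwork", function(x) {
  g <- x@graph
  if (igraph::vcount(g) == 0) stop("cannot partition an empty network")
  mem <- .fastGreedyMembership(g)
  new("ModulePartition",
      membership = setNames(as.integer(mem), igraph::V(g)$name),
      modularity = igraph::modularity(g, mem))
})

# Fast greedy merge path, cut at maximal modularity; ties resolved toward
# fewer modules (the all-in-one partition at Q = 0 beats a numerically
# equal split).
.fastGreedyMembership <- function(g) {
  comm <- igraph::cluster_fast_greedy(
    g, weights = NULL, merges = TRUE, modularity = TRUE)
  qv <- comm$modularity
  best <- max(which(qv >= max(qv) - 1e-10))
  igraph::cut_at(comm, no = igraph::vcount(g) - best + 1L)
}

#' @rdname ModulePartition-accessors
#' @name ModulePartition-accessors
#' @title Accessors for ModulePartition
#' @param x a [ModulePartition-class].
NULL

#' @rdname ModulePartition-accessors
#' @export
setMethod("moduleMembership", "ModulePartition", function(x) x@membership)

#' @rdname ModulePartition-accessors
#' @export
setMethod("moduleSizes", "ModulePartition", function(x)
  table(x@membership))

#' @rdname ModulePartition-accessors
#' @export
setMethod("modularityScore", "ModulePartition", function(x) x@modularity)

setMethod("show", "ModulePartition", function(object) {
  sz <- table(object@membership)
  cat(sprintf("ModulePartition: %d nodes in %d modules, Q = %.4f\n",
              length(object@membership), length(sz), object@modularity))
  cat("module sizes:", paste(sort(as.integer(sz), decreasing = TRUE),
                             collapse = ", "), "\n")
})

#' Topological indices of a co-occurrence network
#'
#' Computes the six standard descriptors of network structure:
#' \describe{
#'   \item{MD}{Newman modularity of the module partition.}
#'   \item{CC}{average local clustering coefficient (triangles over possible
#'     triangles around each node).}
#'   \item{APL}{average shortest-path length over all connected ordered node
#'     pairs (disconnected pairs are excluded, so modular, disconnected
#'     networks still get a finite value).}
#'   \item{ND}{network diameter: the longest shortest path over connected
#'     pairs.}
#'   \item{AD}{average degree, 2E/N.}
#'   \item{GD}{graph density, 2E/(N(N-1)).}
#' }
#'
#' `ccMode` controls how nodes of degree < 2 (whose local clustering is
#' undefined) enter the average: `"exclude"` (default) drops them, the
#' convention of igraph's local clustering average; `"zero"` counts them
#' as 0.
#'
#' @param network a [CoNetwork-class] with at least one edge.
#' @param partition a [ModulePartition-class] for the same network; computed
#'   by [detectModules()] when omitted.
#' @param ccMode `"exclude"` or `"zero"`.
#' @return Named numeric vector: MD, CC, APL, ND, AD, GD, nNodes, nEdges.
#' @export
networkIndices <- function(network, partition = NULL,
                           ccMode = c("exclude", "zero")) {
  ccMode <- match.arg(ccMode)
  stopifnot(is(network, "CoNetwork"))
  g <- network@graph
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0 || m == 0) stop("network has no edges")
  if (is.null(partition)) partition <- detectModules(network)
  mem <- partition@membership[igraph::V(g)$name]
  if (anyNA(mem)) stop("partition does not cover all network nodes")

  cc <- .meanLocalClustering(g, ccMode)
  c(MD = igraph::modularity(g, mem),
    CC = cc,
    APL = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE),
    ND = igraph::diameter(g, directed = FALSE, unconnected = TRUE),
    AD = 2 * m / n,
    GD = 2 * m / (n * (n - 1)),
    nNodes = n,
    nEdges = m)
}

.meanLocalClustering <- function(g, ccMode) {
  lc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (ccMode == "zero") lc[is.nan(lc)] <- 0
  mean(lc[!is.nan(lc)])
}
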