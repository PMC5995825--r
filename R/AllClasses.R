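#' @import methods
#' @importFrom stats cor sd pt pnorm setNames predict smooth.spline p.adjust
#'   rnorm runif rmultinom quantile var optim cor.test t.test
#' @importFrom utils read.delim write.table packageVersion
NULL

setOldClass("igraph")

#' AbundanceTable: OTU abundances with taxonomy and sample metadata
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a mode flag
#' distinguishing raw counts from relative abundances. Rows are OTUs, columns
#' are samples. `rowData` carries the taxonomy (at least `kingdom` and
#' `phylum`; `unclassified` is a valid label at any rank), `colData` carries
#' the group (zone) label and environmental variables.
#'
#' Relative abundances are closed per kingdom block: 16S and 18S amplicons
#' are sequenced separately, so proportions of bacterioplankton and
#' microeukaryote OTUs each sum to one within a sample.
#'
#' @slot abundanceMode `"counts"` or `"relative"`.
#' @seealso [AbundanceTable()] for the constructor.
#' @export
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  slots = c(abundanceMode = "character")
)

setValidity("AbundanceTable", function(object) {
  msg <- character()
  mode <- object@abundanceMode
  if (length(mode) != 1L || !mode %in% c("counts", "relative"))
    msg <- c(msg, "abundanceMode must be 'counts' or 'relative'")
  v <- SummarizedExperiment::assay(object)
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "abundance values must be non-negative")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "OTU ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (!"kingdom" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a 'kingdom' column")
  if (length(mode) == 1L && identical(mode, "relative") && ncol(object) > 0L) {
    kd <- as.character(SummarizedExperiment::rowData(object)$kingdom)
    for (k in unique(kd)) {
      cs <- colSums(v[kd == k, , drop = FALSE])
      if (any(abs(cs - 1) > 1e-9))
        msg <- c(msg, sprintf(
          "relative abundances must sum to 1 per sample within kingdom '%s'", k))
    }
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationScreen: all-pairs Spearman R/P/Q matrices
#'
#' Holds the symmetric Spearman correlation matrix over OTU pairs, the
#' matching two-sided p-value matrix and the false-discovery q-value matrix.
#' The diagonal is excluded from testing (`P` and `Q` diagonal are `NA`).
#' Pairs involving a constant OTU profile carry `NA` correlations and are
#' never eligible as edges.
#'
#' @slot R,P,Q symmetric numeric matrices (OTU x OTU).
#' @slot nSamples number of samples the correlations were computed from.
#' @slot qMethod `"storey"` or `"BH"`.
#' @export
setClass("CorrelationScreen",
  slots = c(R = "matrix", P = "matrix", Q = "matrix",
            nSamples = "integer", qMethod = "character")
)

setValidity("CorrelationScreen", function(object) {
  msg <- character()
  d <- dim(object@R)
  if (!identical(d, dim(object@P)) || !identical(d, dim(object@Q)))
    msg <- c(msg, "R, P and Q must have identical dimensions")
  if (d[1] != d[2]) msg <- c(msg, "R must be square")
  offP <- object@P[upper.tri(object@P)]
  if (any(offP < 0 | offP > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  offQ <- object@Q[upper.tri(object@Q)]
  if (any(offQ < 0 | offQ > 1, na.rm = TRUE))
    msg <- c(msg, "q-values must lie in [0, 1]")
  ok <- !is.na(object@R)
  if (!isTRUE(all.equal(object@R[ok], t(object@R)[ok], tolerance = 1e-12)))
    msg <- c(msg, "R must be symmetric")
  if (length(msg)) msg else TRUE
})

#' CoNetwork: signed co-occurrence network
#'
#' Undirected simple graph whose nodes are OTUs and whose edges are strong,
#' significant pairwise correlations. Edge records keep the correlation, its
#' p- and q-value, the sign, and whether the edge joins OTUs of the same
#' kingdom (`intra`) or different kingdoms (`inter`). Node records keep
#' kingdom, phylum and mean relative abundance (%). Nodes without any
#' surviving edge are dropped at construction.
#'
#' @slot graph an `igraph` object (undirected, simple).
#' @slot edges data.frame: otu_a, otu_b, rho, p, q, sign, kingdom_pair.
#' @slot nodes data.frame keyed by OTU id: kingdom, phylum, mean_abundance.
#' @seealso [buildNetwork()], [CoNetwork()]
#' @export
setClass("CoNetwork",
  slots = c(graph = "igraph", edges = "data.frame", nodes = "data.frame")
)

setValidity("CoNetwork", function(object) {
  msg <- character()
  g <- object@graph
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::any_loop(g)) msg <- c(msg, "graph must have no self-loops")
  if (igraph::any_multiple(g)) msg <- c(msg, "graph must be simple")
  if (igraph::vcount(g) != nrow(object@nodes))
    msg <- c(msg, "node table must match graph vertex count")
  if (igraph::ecount(g) != nrow(object@edges))
    msg <- c(msg, "edge table must match graph edge count")
  if (length(msg)) msg else TRUE
})

#' ModulePartition: module assignment of network nodes
#'
#' @slot membership named integer vector, node id -> module id.
#' @slot modularity Newman modularity Q of the partition.
#' @seealso [detectModules()]
#' @export
setClass("ModulePartition",
  slots = c(membership = "integer", modularity = "numeric")
)

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by node id")
  if (length(object@modularity) != 1L)
    msg <- c(msg, "modularity must be a single number")
  else if (!is.na(object@modularity) &&
           (object@modularity < -0.5 || object@modularity > 1))
    msg <- c(msg, "modularity must lie in [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' NullEnsembleSummary: random-network ensemble statistics
#'
#' Mean and standard deviation of topological indices over an ensemble of
#' random networks with the same numbers of nodes and edges as an empirical
#' network, plus the per-replicate index values.
#'
#' @slot model `"gnm"` (uniform G(n,m)) or `"degree_preserving_swap"`.
#' @slot nReplicates ensemble size.
#' @slot stats data.frame: index, mean, sd.
#' @slot replicates numeric matrix, replicates x indices.
#' @slot seed integer seed used (NA if none supplied).
#' @seealso [randomEnsemble()], [zTest()]
#' @export
setClass("NullEnsembleSummary",
  slots = c(model = "character", nReplicates = "integer",
            stats = "data.frame", replicates = "matrix", seed = "integer")
)

setValidity("NullEnsembleSummary", function(object) {
  msg <- character()
  if (!object@model %in% c("gnm", "degree_preserving_swap"))
    msg <- c(msg, "model must be 'gnm' or 'degree_preserving_swap'")
  if (nrow(object@replicates) != object@nReplicates)
    msg <- c(msg, "replicate matrix must have nReplicates rows")
  if (any(object@stats$sd < 0, na.rm = TRUE))
    msg <- c(msg, "standard deviations must be non-negative")
  if (length(msg)) msg else TRUE
})
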