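#' Build the signed co-occurrence network
#'
#' Keeps an OTU pair as an edge iff `|rho| >= rMin` AND `p < pMax` AND
#' `q < qMax` (defaults 0.9, 0.01, 0.05). Edges are canonically oriented
#' with `otu_a < otu_b` lexicographically; OTUs without any surviving edge
#' are dropped. Edges are tagged with their sign and with `intra`/`inter`
#' kingdom pairing.
#'
#' @param screen a [CorrelationScreen-class].
#' @param table the [AbundanceTable-class] the screen was computed from
#'   (relative mode); supplies taxonomy and mean relative abundance.
#' @param rMin,pMax,qMax retention thresholds.
#' @param splitProteobacteria resolve Proteobacteria to class level in node
#'   phylum labels (see [phylumLabels()]).
#' @return A [CoNetwork-class].
#' @examples
#' tab <- toRelative(simulateDataset(
#'   syntheticConfig(nOtus = 30, moduleSizes = c(10, 10), seed = 4)))
#' zoneB <- tab[, zones(tab) == "zoneB"]
#' net <- buildNetwork(spearmanScreen(zoneB), zoneB)
#' net
#' @export
buildNetwork <- function(screen, table, rMin = 0.9, pMax = 0.01, qMax = 0.05,
                         splitProteobacteria = TRUE) {
  stopifnot(is(screen, "CorrelationScreen"), is(table, "AbundanceTable"))
  R <- screen@R
  ids <- rownames(R)
  if (!all(ids %in% rownames(table)))
    stop("screen OTUs missing from the abundance table")

  ut <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[ut]
  p <- screen@P[ut]
  q <- screen@Q[ut]
  keep <- !is.na(rho) & !is.na(q) & abs(rho) >= rMin & p < pMax & q < qMax
  ut <- ut[keep, , drop = FALSE]

  a <- ids[ut[, 1]]
  b <- ids[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  kingdom <- setNames(
    as.character(SummarizedExperiment::rowData(table)$kingdom),
    rownames(table))
  edges <- data.frame(
    otu_a = a, otu_b = b,
    rho = rho[keep], p = p[keep], q = q[keep],
    sign = ifelse(rho[keep] > 0, "positive", "negative"),
    kingdom_pair = ifelse(kingdom[a] == kingdom[b], "intra", "inter"),
    stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
  rownames(edges) <- NULL

  nodeIds <- ids[ids %in% c(edges$otu_a, edges$otu_b)]
  phy <- phylumLabels(table, splitProteobacteria = splitProteobacteria)
  meanAb <- rowMeans(SummarizedExperiment::assay(table)) * 100
  nodes <- data.frame(
    kingdom = unname(kingdom[nodeIds]),
    phylum = unname(phy[nodeIds]),
    mean_abundance = unname(meanAb[nodeIds]),
    row.names = nodeIds, stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodeIds, nodes))
  new("CoNetwork", graph = g, edges = edges, nodes = nodes)
}

#' Construct a CoNetwork from an igraph object
#'
#' Wraps an arbitrary undirected simple graph as a [CoNetwork-class], e.g.
#' for analysing networks imported from elsewhere. Node attributes `kingdom`,
#' `phylum` and `mean_abundance` and edge attributes `rho`/`sign` are taken
#' from the graph when present, otherwise filled with defaults (kingdom
#' `"bacterioplankton"`, phylum `"unclassified"`, positive sign).
#'
#' @param graph an undirected simple `igraph` object with named vertices
#'   (unnamed vertices are named `V1`, `V2`, ...).
#' @param phylum optional named character vector overriding node phyla.
#' @param dropIsolated drop zero-degree vertices (default TRUE, the
#'   behaviour of [buildNetwork()]); keep them e.g. for combinatorial
#'   fixtures where the node universe matters.
#' @return A [CoNetwork-class].
#' @export
CoNetwork <- function(graph, phylum = NULL, dropIsolated = TRUE) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph)
  graph <- igraph::simplify(graph)
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- paste0("V", seq_len(igraph::vcount(graph)))
  if (dropIsolated)
    graph <- igraph::delete_vertices(graph, igraph::degree(graph) == 0)

  nm <- igraph::V(graph)$name
  getAttr <- function(attr, default) {
    v <- igraph::vertex_attr(graph, attr)
    if (is.null(v)) rep(default, length(nm)) else v
  }
  nodes <- data.frame(
    kingdom = getAttr("kingdom", "bacterioplankton"),
    phylum = getAttr("phylum", "unclassified"),
    mean_abundance = getAttr("mean_abundance", NA_real_),
    row.names = nm, stringsAsFactors = FALSE)
  if (!is.null(phylum)) {
    common <- intersect(names(phylum), rownames(nodes))
    nodes[common, "phylum"] <- unname(phylum[common])
  }

  el <- igraph::as_edgelist(graph)
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  rho <- igraph::edge_attr(graph, "rho")
  if (is.null(rho)) rho <- rep(NA_real_, nrow(el))
  sgn <- igraph::edge_attr(graph, "sign")
  if (is.null(sgn))
    sgn <- ifelse(!is.na(rho) & rho < 0, "negative", "positive")
  edges <- data.frame(
    otu_a = a, otu_b = b, rho = rho, p = NA_real_, q = NA_real_,
    sign = sgn,
    kingdom_pair = ifelse(nodes[a, "kingdom"] == nodes[b, "kingdom"],
                          "intra", "inter"),
    stringsAsFactors = FALSE)
  ord <- order(edges$otu_a, edges$otu_b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  igraph::V(graph)$phylum <- nodes$phylum
  igraph::V(graph)$kingdom <- nodes$kingdom
  new("CoNetwork", graph = graph, edges = edges, nodes = nodes)
}

#' @rdname CoNetwork-accessors
#' @name CoNetwork-accessors
#' @title Accessors for CoNetwork
#' @param x a [CoNetwork-class].
#' @return `networkGraph()` the underlying igraph; `edgeTable()` /
#'   `nodeTable()` the edge and node data.frames.
NULL

#' @rdname CoNetwork-accessors
#' @export
setMethod("networkGraph", "CoNetwork", function(x) x@graph)

#' @rdname CoNetwork-accessors
#' @export
setMethod("edgeTable", "CoNetwork", function(x) x@edges)

#' @rdname CoNetwork-accessors
#' @export
setMethod("nodeTable", "CoNetwork", function(x) x@nodes)

setMethod("show", "CoNetwork", function(object) {
  e <- object@edges
  cat(sprintf("CoNetwork: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(object@nodes), nrow(e),
              sum(e$sign == "positive"), sum(e$sign == "negative")))
  if (nrow(e))
    cat(sprintf("kingdom pairing: %d intra, %d inter\n",
                sum(e$kingdom_pair == "intra"),
                sum(e$kingdom_pair == "inter")))
})

#' Fit degree-distribution models
#'
#' Fits the empirical degree distribution P(k) (fraction of nodes with
#' degree k, k >= 1) by least squares on the log scale under three models:
#' power law `log P = a - alpha log k`, exponential
#' `log P = a - k / kappa`, and truncated power law
#' `log P = a - alpha log k - k / kappa`. The model with the highest R
#' squared is selected; because the truncated model nests the other two,
#' its R squared is never lower. Scale-free-like ecological networks
#' typically select the truncated power law.
#'
#' @param x a [CoNetwork-class], or a numeric vector of node degrees.
#' @return list with class `degreeFit`: `fits` (data.frame with model,
#'   alpha, kappa, intercept, r_squared) and `best_model`; `NULL` fits with
#'   a warning when fewer than 3 distinct degrees are available.
#' @export
fitDegreeDistribution <- function(x) {
  k <- if (is(x, "CoNetwork")) igraph::degree(x@graph) else as.numeric(x)
  k <- k[k >= 1]
  if (length(k) < 10)
    stop("at least 10 nodes with degree >= 1 are required")
  tab <- table(k)
  kk <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(k)
  if (length(kk) < 3) {
    warning("fewer than 3 distinct degrees; degree-distribution fit skipped")
    return(structure(list(fits = NULL, best_model = NA_character_),
                     class = "degreeFit"))
  }
  y <- log(pk); lx <- log(kk)
  fits <- list(
    power = lm(y ~ lx),
    exponential = lm(y ~ kk),
    truncated = lm(y ~ lx + kk))
  res <- data.frame(
    model = names(fits),
    alpha = c(-coef(fits$power)[["lx"]], NA,
              -coef(fits$truncated)[["lx"]]),
    kappa = c(NA, -1 / coef(fits$exponential)[["kk"]],
              -1 / coef(fits$truncated)[["kk"]]),
    intercept = vapply(fits, function(f) coef(f)[["(Intercept)"]], 0),
    r_squared = vapply(fits, function(f) summary(f)$r.squared, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fits = res,
                 best_model = res$model[which.max(res$r_squared)]),
            class = "degreeFit")
}

#' @export
print.degreeFit <- function(x, ...) {
  if (is.null(x$fits)) {
    cat("degree-distribution fit: skipped (too few distinct degrees)\n")
  } else {
    print(x$fits, digits = 4)
    cat("best model by R squared:", x$best_model, "\n")
  }
  invisible(x)
}

#' @importFrom stats lm coef
NULL
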