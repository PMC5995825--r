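# Canonical unordered phylum-pair key.
.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Edge counts per unordered phylum pair; `pairs` fixes the universe/order.
.pairCounts <- function(endsA, endsB, pairs) {
  key <- .pairKey(endsA, endsB)
  cnt <- setNames(numeric(nrow(pairs)),
                  .pairKey(pairs$phylum_a, pairs$phylum_b))
  tab <- table(key)
  cnt[names(tab)] <- as.numeric(tab)
  unname(cnt)
}

# All unordered pairs (incl. a = a) over the phyla present among nodes.
.phylumPairs <- function(phyla) {
  u <- sort(unique(phyla))
  idx <- which(upper.tri(diag(length(u)), diag = TRUE), arr.ind = TRUE)
  data.frame(phylum_a = u[idx[, 1]], phylum_b = u[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Observed incidence of co-occurrence between phyla
#'
#' For the edges of one sign, the observed incidence O(a, b) is the relative
#' percentage of edges joining phylum a with phylum b:
#' 100 x (number of sign-matching edges with one endpoint in a and the other
#' in b) / (total sign-matching edges). Intra-phylum incidence uses a = b.
#' Incidences of one sign sum to 100.
#'
#' @param network a [CoNetwork-class] whose nodes all carry a phylum
#'   (`unclassified` is a valid label).
#' @param sign `"positive"` or `"negative"`.
#' @return data.frame: phylum_a, phylum_b (a <= b), n_edges, o (percent).
#'   When no edge of the requested sign exists, a zero-row frame with
#'   attribute `no_edges = TRUE` is returned.
#' @export
observedIncidence <- function(network, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(is(network, "CoNetwork"))
  phy <- setNames(network@nodes$phylum, rownames(network@nodes))
  pairs <- .phylumPairs(phy)
  e <- network@edges[network@edges$sign == sign, , drop = FALSE]
  if (nrow(e) == 0) {
    out <- cbind(pairs[0, ], n_edges = numeric(0), o = numeric(0))
    attr(out, "no_edges") <- TRUE
    return(out)
  }
  cnt <- .pairCounts(phy[e$otu_a], phy[e$otu_b], pairs)
  out <- cbind(pairs, n_edges = cnt, o = 100 * cnt / nrow(e))
  attr(out, "no_edges") <- FALSE
  out
}

#' O/R co-occurrence ratio against a random-network ensemble
#'
#' Compares the observed incidence O of same-sign edges between phylum
#' pairs to the random incidence R, the mean incidence over random networks
#' with the same numbers of nodes and edges as the whole empirical network
#' (node phylum labels kept fixed, all edges randomized; random edges carry
#' no sign, so R is shared between the signs). O/R > 1 indicates more
#' co-occurrence (or co-exclusion, for negative edges) between the two taxa
#' than expected at random. The empirical p-value uses the add-one
#' correction: for O/R > 1, p = (1 + # replicates with incidence >= O) /
#' (n + 1), mirrored for O/R < 1.
#'
#' @param network a [CoNetwork-class].
#' @param sign `"positive"` or `"negative"`.
#' @param nRandom ensemble size (default 1000).
#' @param model `"gnm"` or `"degree_preserving_swap"`.
#' @param seed integer seed (optional).
#' @return data.frame: phylum_a, phylum_b, sign, n_edges, o, r, ratio
#'   (NA where R = 0), p, n_random. All-NA with attribute `no_edges` when
#'   the network has no edge of the requested sign.
#' @export
orRatio <- function(network, sign = c("positive", "negative"),
                    nRandom = 1000, model = c("gnm", "degree_preserving_swap"),
                    seed = NULL) {
  sign <- match.arg(sign)
  model <- match.arg(model)
  stopifnot(is(network, "CoNetwork"))
  if (!is.null(seed)) set.seed(seed)
  obs <- observedIncidence(network, sign)
  pairs <- obs[, c("phylum_a", "phylum_b"), drop = FALSE]
  if (isTRUE(attr(obs, "no_edges"))) {
    pairs <- .phylumPairs(network@nodes$phylum)
    out <- cbind(pairs, sign = sign, n_edges = 0, o = NA_real_,
                 r = NA_real_, ratio = NA_real_, p = NA_real_,
                 n_random = nRandom)
    attr(out, "no_edges") <- TRUE
    return(out)
  }

  g0 <- network@graph
  N <- igraph::vcount(g0)
  E <- igraph::ecount(g0)
  phyByIndex <- network@nodes$phylum   # labels fixed to node positions

  rSum <- numeric(nrow(pairs))
  nGE <- numeric(nrow(pairs))   # replicates with incidence >= observed
  nLE <- numeric(nrow(pairs))
  for (i in seq_len(nRandom)) {
    g <- if (model == "gnm") igraph::sample_gnm(N, E)
         else igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * E))
    el <- igraph::as_edgelist(g, names = FALSE)
    inc <- 100 * .pairCounts(phyByIndex[el[, 1]], phyByIndex[el[, 2]],
                             pairs) / nrow(el)
    rSum <- rSum + inc
    nGE <- nGE + (inc >= obs$o - 1e-12)
    nLE <- nLE + (inc <= obs$o + 1e-12)
  }
  r <- rSum / nRandom
  ratio <- ifelse(r == 0, NA_real_, obs$o / r)
  p <- ifelse(is.na(ratio), NA_real_,
        ifelse(ratio > 1, (1 + nGE) / (nRandom + 1),
        ifelse(ratio < 1, (1 + nLE) / (nRandom + 1), 1)))
  out <- cbind(pairs, sign = sign, n_edges = obs$n_edges, o = obs$o,
               r = r, ratio = ratio, p = p, n_random = nRandom)
  attr(out, "no_edges") <- FALSE
  out
}
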