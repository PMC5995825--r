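# Indices on a bare igraph, used per random-network replicate.
.graphIndices <- function(g, indices, ccMode = "exclude") {
  out <- setNames(numeric(length(indices)), indices)
  for (idx in indices) {
    out[idx] <- switch(idx,
      MD = igraph::modularity(g, .fastGreedyMembership(g)),
      CC = .meanLocalClustering(g, ccMode),
      APL = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE),
      ND = igraph::diameter(g, directed = FALSE, unconnected = TRUE),
      AD = 2 * igraph::ecount(g) / igraph::vcount(g),
      GD = 2 * igraph::ecount(g) /
        (igraph::vcount(g) * (igraph::vcount(g) - 1)),
      stop("unknown index: ", idx))
  }
  out
}

#' Random-network ensemble summary
#'
#' Generates `n` random networks with the same numbers of nodes and edges
#' as the empirical network and summarizes the chosen topological indices
#' over the ensemble (mean and SD). Two null models are available:
#' `"gnm"` draws a uniform simple graph G(N, E) (the default: in uniform
#' random graphs the expected clustering equals the density, the signature
#' observed in typical published random-network columns), and
#' `"degree_preserving_swap"` rewires the empirical graph by double-edge
#' swaps (10 E swap attempts), preserving every node's degree.
#' Modularity per replicate is recomputed with fast greedy optimization.
#'
#' @param network a [CoNetwork-class].
#' @param n ensemble size (default 1000; >= 2).
#' @param model `"gnm"` or `"degree_preserving_swap"`.
#' @param seed integer seed for reproducibility (optional).
#' @param indices which indices to track (any of MD, CC, APL, ND).
#' @param ccMode clustering convention, see [networkIndices()].
#' @return A [NullEnsembleSummary-class].
#' @export
randomEnsemble <- function(network, n = 1000,
                           model = c("gnm", "degree_preserving_swap"),
                           seed = NULL,
                           indices = c("MD", "CC", "APL", "ND"),
                           ccMode = c("exclude", "zero")) {
  model <- match.arg(model)
  ccMode <- match.arg(ccMode)
  stopifnot(is(network, "CoNetwork"))
  if (n < 2) stop("ensemble size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  g0 <- network@graph
  N <- igraph::vcount(g0)
  E <- igraph::ecount(g0)
  reps <- matrix(NA_real_, nrow = n, ncol = length(indices),
                 dimnames = list(NULL, indices))
  for (i in seq_len(n)) {
    g <- if (model == "gnm") igraph::sample_gnm(N, E)
         else igraph::rewire(g0, igraph::keeping_degseq(niter = 10 * E))
    reps[i, ] <- .graphIndices(g, indices, ccMode)
  }
  stats <- data.frame(
    index = indices,
    mean = colMeans(reps),
    sd = apply(reps, 2, sd),
    row.names = NULL, stringsAsFactors = FALSE)
  new("NullEnsembleSummary", model = model, nReplicates = as.integer(n),
      stats = stats, replicates = reps,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname NullEnsembleSummary-accessors
#' @name NullEnsembleSummary-accessors
#' @title Accessors for NullEnsembleSummary
#' @param x a [NullEnsembleSummary-class].
NULL

#' @rdname NullEnsembleSummary-accessors
#' @export
setMethod("nullStats", "NullEnsembleSummary", function(x) x@stats)

#' @rdname NullEnsembleSummary-accessors
#' @export
setMethod("nullReplicates", "NullEnsembleSummary", function(x) x@replicates)

setMethod("show", "NullEnsembleSummary", function(object) {
  cat(sprintf("NullEnsembleSummary: %d replicates of model '%s'\n",
              object@nReplicates, object@model))
  print(object@stats, digits = 4)
})

#' Z-test of an observed index against a random-network ensemble
#'
#' Z = (observed - null mean) / null SD, with a two-sided p-value from the
#' standard normal. A degenerate ensemble (SD = 0) yields p = 1 when the
#' observed value equals the null mean and p = 0 otherwise, flagged in the
#' output.
#'
#' @param observed observed index value (scalar).
#' @param summary a [NullEnsembleSummary-class].
#' @param index index name present in the ensemble summary.
#' @return one-row data.frame: index, observed, null_mean, null_sd, z, p,
#'   degenerate.
#' @export
zTest <- function(observed, summary, index) {
  stopifnot(is(summary, "NullEnsembleSummary"))
  st <- summary@stats
  row <- match(index, st$index)
  if (is.na(row))
    stop(sprintf("index '%s' not in ensemble summary (have: %s)", index,
                 paste(st$index, collapse = ", ")))
  mu <- st$mean[row]; s <- st$sd[row]
  if (s > 0) {
    z <- (observed - mu) / s
    p <- 2 * pnorm(-abs(z))
    degenerate <- FALSE
  } else {
    z <- NA_real_
    p <- if (isTRUE(all.equal(observed, mu))) 1 else 0
    degenerate <- TRUE
  }
  data.frame(index = index, observed = observed, null_mean = mu,
             null_sd = s, z = z, p = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

# Fast matrix-level pipeline: prevalence filter -> per-kingdom proportions
# -> Spearman screen -> thresholded graph -> indices. Used by the resampling
# loops of compareZones(), where per-replicate S4 container overhead counts.
# Returns NULL when the network comes out empty.
.fastZoneIndices <- function(counts, kingdom, minPrevalence, rMin, pMax,
                             qMax, indices, ccMode) {
  keep <- rowSums(counts > 0) >= minPrevalence
  if (sum(keep) < 2) return(NULL)
  v <- counts[keep, , drop = FALSE]
  kd <- kingdom[keep]
  for (k in unique(kd)) {
    rows <- kd == k
    tot <- colSums(v[rows, , drop = FALSE])
    if (any(tot == 0)) return(NULL)
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, tot, "/")
  }
  R <- .spearmanMatrix(v)
  P <- .spearmanPvalue(R, ncol(v))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[ut]
  p <- P[ut]
  ok <- !is.na(rho)
  if (!any(ok)) return(NULL)
  q <- rep(NA_real_, length(rho))
  q[ok] <- storeyQvalues(p[ok])
  pass <- ok & abs(rho) >= rMin & p < pMax & q < qMax
  if (!any(pass)) return(NULL)
  g <- igraph::graph_from_edgelist(ut[pass, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  .graphIndices(g, indices, ccMode)
}

#' Compare network indices between two zones
#'
#' A single network per zone yields a single value of each index, so a
#' direct two-sample test is not defined; the comparison must quantify how
#' much the indices would vary under resampling of the zone's samples.
#' Two resampling schemes are provided:
#' \describe{
#'   \item{permutation (default)}{zone labels are shuffled across the
#'     pooled samples `nResample` times, the full pipeline (prevalence
#'     filter, relative abundance, Spearman screen, thresholding) is re-run
#'     on both permuted groups, and the two-sided p-value per index is the
#'     add-one-corrected fraction of permutations whose absolute index
#'     difference reaches the observed one. Calibrated by construction
#'     under exchangeability of samples between zones.}
#'   \item{bootstrap}{columns of each zone are resampled with replacement
#'     `nResample` times; the statistic is
#'     t = (I1 - I2) / sqrt(s1^2 + s2^2) with s the bootstrap SDs
#'     (`method = "bootstrap_se"`), or a Welch t-test on the raw replicate
#'     distributions (`method = "welch"`; note that treating bootstrap
#'     replicates as independent observations is strongly
#'     anticonservative).}
#' }
#' Resamples whose networks come out empty are dropped and counted; more
#' than 50% drops is an error.
#'
#' @param table an [AbundanceTable-class] in counts mode containing both
#'   zones.
#' @param zonePair character(2): the two zone labels (default: first two).
#' @param nResample permutations or bootstrap replicates (>= 2; >= 99
#'   recommended for the permutation test).
#' @param seed integer seed (optional).
#' @param minPrevalence,rMin,pMax,qMax pipeline thresholds.
#' @param indices indices to compare.
#' @param method `"permutation"` (default), `"bootstrap_se"` or `"welch"`.
#' @param ccMode clustering convention, see [networkIndices()].
#' @return data.frame, one row per index: observed values per zone, the
#'   test statistic (observed difference for the permutation test),
#'   p-value, and resampling diagnostics. Attributes `zones` and `method`.
#' @export
compareZones <- function(table, zonePair = NULL, nResample = 99,
                         seed = NULL, minPrevalence = 8, rMin = 0.9,
                         pMax = 0.01, qMax = 0.05,
                         indices = c("MD", "CC", "APL", "ND", "AD", "GD"),
                         method = c("permutation", "bootstrap_se", "welch"),
                         ccMode = c("exclude", "zero")) {
  method <- match.arg(method)
  ccMode <- match.arg(ccMode)
  stopifnot(is(table, "AbundanceTable"))
  if (nResample < 2)
    stop("nResample must be at least 2 (resampling degrees of freedom)")
  zn <- zones(table)
  if (is.null(zonePair)) zonePair <- unique(zn)[1:2]
  if (length(zonePair) != 2 || !all(zonePair %in% zn))
    stop("zonePair must name two zones present in the table")
  if (!is.null(seed)) set.seed(seed)

  counts <- SummarizedExperiment::assay(table)
  kingdom <- as.character(SummarizedExperiment::rowData(table)$kingdom)
  cols1 <- which(zn == zonePair[1])
  cols2 <- which(zn == zonePair[2])
  run <- function(cols)
    .fastZoneIndices(counts[, cols, drop = FALSE], kingdom, minPrevalence,
                     rMin, pMax, qMax, indices, ccMode)
  obs1 <- run(cols1)
  obs2 <- run(cols2)
  if (is.null(obs1) || is.null(obs2))
    stop(sprintf("zone '%s' yields an empty network",
                 zonePair[if (is.null(obs1)) 1 else 2]))

  if (method == "permutation") {
    d0 <- abs(obs1 - obs2)
    hits <- setNames(numeric(length(indices)), indices)
    used <- 0L
    pooled <- c(cols1, cols2)
    for (i in seq_len(nResample)) {
      perm <- sample(pooled)
      p1 <- run(perm[seq_along(cols1)])
      p2 <- run(perm[length(cols1) + seq_along(cols2)])
      if (is.null(p1) || is.null(p2)) next
      used <- used + 1L
      hits <- hits + (abs(p1 - p2) >= d0 - 1e-12)
    }
    if (used < nResample / 2)
      stop("more than half of the permutation networks were empty")
    out <- data.frame(
      index = indices, observed_1 = unname(obs1[indices]),
      observed_2 = unname(obs2[indices]),
      statistic = unname((obs1 - obs2)[indices]),
      p = unname((1 + hits[indices]) / (used + 1)),
      n_used = used, dropped = nResample - used,
      stringsAsFactors = FALSE)
  } else {
    boot <- lapply(list(cols1, cols2), function(cols) {
      b <- matrix(NA_real_, nResample, length(indices),
                  dimnames = list(NULL, indices))
      for (i in seq_len(nResample)) {
        bi <- run(sample(cols, replace = TRUE))
        if (!is.null(bi)) b[i, ] <- bi
      }
      dropped <- sum(is.na(b[, 1]))
      if (dropped > nResample / 2)
        stop("more than half of the bootstrap networks were empty")
      list(b = b[!is.na(b[, 1]), , drop = FALSE], dropped = dropped)
    })
    rows <- lapply(indices, function(idx) {
      o1 <- obs1[idx]; o2 <- obs2[idx]
      b1 <- boot[[1]]$b[, idx]; b2 <- boot[[2]]$b[, idx]
      s1 <- sd(b1); s2 <- sd(b2)
      if (method == "bootstrap_se") {
        se <- sqrt(s1^2 + s2^2)
        if (se == 0) {
          stat <- NA_real_; df <- NA_real_
          p <- if (isTRUE(all.equal(unname(o1), unname(o2)))) 1 else 0
        } else {
          stat <- unname(o1 - o2) / se
          df <- se^4 / (s1^4 / (length(b1) - 1) + s2^4 / (length(b2) - 1))
          p <- 2 * pt(-abs(stat), df = df)
        }
      } else {
        tt <- t.test(b1, b2)
        stat <- unname(tt$statistic); df <- unname(tt$parameter)
        p <- tt$p.value
      }
      data.frame(index = idx, observed_1 = unname(o1),
                 observed_2 = unname(o2), boot_sd_1 = s1, boot_sd_2 = s2,
                 statistic = stat, df = df, p = p,
                 dropped_1 = boot[[1]]$dropped,
                 dropped_2 = boot[[2]]$dropped, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "zones") <- zonePair
  attr(out, "method") <- method
  out
}
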