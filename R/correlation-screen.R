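# Spearman rho between the rows of a matrix: Pearson correlation of average
# ranks (the tie-corrected form). Rows with zero rank variance give NA.
.spearmanMatrix <- function(values) {
  ranks <- t(apply(values, 1, rank))
  const <- apply(ranks, 1, function(r) all(r == r[1]))
  R <- suppressWarnings(cor(t(ranks)))
  R[const, ] <- NA_real_
  R[, const] <- NA_real_
  diag(R) <- 1
  R
}

# Two-sided p-value for Spearman rho via the t distribution with n-2 df.
.spearmanPvalue <- function(rho, n) {
  p <- rho
  ok <- !is.na(rho)
  r <- pmin(pmax(rho[ok], -1), 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tstat[abs(r) >= 1] <- Inf
  p[ok] <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p
}

#' All-pairs Spearman correlation screen
#'
#' Computes Spearman rank correlations (average ranks with tie correction)
#' between all OTU pairs of a relative-abundance table, two-sided p-values
#' from the t-distribution approximation with n - 2 degrees of freedom, and
#' false-discovery q-values over the pool of testable pairs.
#'
#' Constant OTU profiles have undefined rank correlation; their pairs are
#' recorded as `rho = NA`, `p = 1`, are excluded from the q-value pool, and
#' can never become edges. With `pMethod = "exact"` p-values come from
#' [stats::cor.test()]'s exact null distribution (feasible for small sample
#' numbers; falls back to the t approximation in the presence of ties).
#'
#' @param x an [AbundanceTable-class] in relative mode with >= 4 samples.
#' @param pMethod `"t"` (default) or `"exact"`.
#' @param qMethod `"storey"` (default, smoother pi0 estimate) or `"BH"`.
#' @return A [CorrelationScreen-class] with matrices `R`, `P`, `Q`.
#' @examples
#' tab <- toRelative(simulateDataset(
#'   syntheticConfig(nOtus = 30, moduleSizes = c(10, 10), seed = 4)))
#' scr <- spearmanScreen(tab[, zones(tab) == "zoneA"])
#' scr
#' @export
setMethod("spearmanScreen", "AbundanceTable",
  function(x, pMethod = c("t", "exact"), qMethod = c("storey", "BH")) {
    pMethod <- match.arg(pMethod)
    qMethod <- match.arg(qMethod)
    if (abundanceMode(x) != "relative")
      stop("spearmanScreen() expects a table in relative mode")
    n <- ncol(x)
    if (n < 4) stop("at least 4 samples are required")
    v <- SummarizedExperiment::assay(x)
    R <- .spearmanMatrix(v)
    if (pMethod == "t") {
      P <- .spearmanPvalue(R, n)
    } else {
      P <- matrix(NA_real_, nrow(v), nrow(v), dimnames = dimnames(R))
      for (i in seq_len(nrow(v) - 1)) for (j in (i + 1):nrow(v)) {
        if (is.na(R[i, j])) next
        P[i, j] <- P[j, i] <- suppressWarnings(
          cor.test(v[i, ], v[j, ], method = "spearman",
                   exact = TRUE)$p.value)
      }
    }
    P[is.na(R)] <- 1
    diag(P) <- NA_real_

    Q <- matrix(NA_real_, nrow(v), nrow(v), dimnames = dimnames(R))
    ut <- upper.tri(R)
    pool <- ut & !is.na(R)   # NA correlations carry no test
    if (any(pool)) {
      q <- if (qMethod == "storey") storeyQvalues(P[pool])
           else p.adjust(P[pool], method = "BH")
      Q[pool] <- q
      Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
    }
    new("CorrelationScreen", R = R, P = P, Q = Q,
        nSamples = as.integer(n), qMethod = qMethod)
  })

setMethod("show", "CorrelationScreen", function(object) {
  m <- nrow(object@R)
  ut <- upper.tri(object@R)
  tested <- sum(ut & !is.na(object@R))
  cat(sprintf(
    "CorrelationScreen: %d OTUs, %d testable pairs, n = %d samples, q = %s\n",
    m, tested, object@nSamples, object@qMethod))
})

#' Storey q-values with smoother pi0 estimation
#'
#' Converts p-values into q-values, the fraction of false positives expected
#' if every test at least as significant is called. The proportion of true
#' nulls pi0 is estimated by the smoother method: pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda)) over the grid lambda = 0.05, 0.10, ...,
#' 0.95, smoothed by a natural cubic spline (3 df) and evaluated at the
#' largest lambda, clamped to (0, 1]. Then
#' q(i) = min over p(j) >= p(i) of pi0 * m * p(j) / rank(p(j)),
#' which is monotone non-decreasing in p.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs are propagated).
#' @param lambdaGrid grid for the pi0 smoother.
#' @return numeric vector of q-values, same length and order as `p`, with
#'   attribute `pi0`.
#' @examples
#' q <- storeyQvalues(c(0.001, 0.02, 0.5, 0.8))
#' attr(q, "pi0")
#' @export
storeyQvalues <- function(p, lambdaGrid = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0L) return(numeric(0))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  if (m == 0L) return(out)
  if (m < 2L || max(pv) < min(lambdaGrid)) {
    pi0 <- 1    # too little information to estimate pi0
  } else {
    pi0l <- vapply(lambdaGrid, function(l) mean(pv > l) / (1 - l), 0)
    fit <- suppressWarnings(smooth.spline(lambdaGrid, pi0l, df = 3))
    pi0 <- predict(fit, x = max(lambdaGrid))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pv, decreasing = TRUE)
  q <- pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  res <- numeric(m)
  res[o] <- q
  out[ok] <- res
  attr(out, "pi0") <- pi0
  out
}
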