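#' Significant OTU-environment correlations
#'
#' Spearman correlation between each OTU's relative-abundance profile and
#' each environmental variable; an (OTU, variable) pair is retained as an
#' environment edge when `|rho| >= rMin` and `p < pMax` (defaults 0.6 and
#' 0.05; p-values are not FDR-adjusted here). Constant environmental
#' variables are skipped with a warning.
#'
#' @param table an [AbundanceTable-class] in relative mode.
#' @param env numeric matrix, samples x variables; defaults to the numeric
#'   columns of `colData(table)`. Sample order must match the table.
#' @param rMin,pMax retention thresholds.
#' @return data.frame: variable, otu, rho, p, sign (retained pairs only).
#' @export
envEdges <- function(table, env = NULL, rMin = 0.6, pMax = 0.05) {
  stopifnot(is(table, "AbundanceTable"))
  if (abundanceMode(table) != "relative")
    stop("envEdges() expects a table in relative mode")
  if (is.null(env)) env <- envData(table)
  env <- as.matrix(env)
  if (nrow(env) != ncol(table))
    stop("env must have one row per sample of the table")
  n <- ncol(table)

  keepVar <- apply(env, 2, function(v) length(unique(v)) > 1)
  if (any(!keepVar))
    warning("constant environmental variable(s) skipped: ",
            paste(colnames(env)[!keepVar], collapse = ", "))
  env <- env[, keepVar, drop = FALSE]
  if (ncol(env) == 0) return(data.frame(variable = character(),
    otu = character(), rho = numeric(), p = numeric(),
    sign = character(), stringsAsFactors = FALSE))

  otuRanks <- t(apply(SummarizedExperiment::assay(table), 1, rank))
  envRanks <- apply(env, 2, rank)
  constOtu <- apply(otuRanks, 1, function(r) all(r == r[1]))
  R <- suppressWarnings(cor(t(otuRanks), envRanks))   # OTUs x variables
  R[constOtu, ] <- NA_real_
  P <- .spearmanPvalue(R, n)

  idx <- which(!is.na(R) & abs(R) >= rMin & P < pMax, arr.ind = TRUE)
  out <- data.frame(
    variable = colnames(env)[idx[, 2]],
    otu = rownames(R)[idx[, 1]],
    rho = R[idx], p = P[idx],
    sign = ifelse(R[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  out[order(out$variable, out$otu), , drop = FALSE]
}

#' Module eigengene
#'
#' The eigengene summarizes a module by a single per-sample profile: each
#' member OTU's relative-abundance profile is standardized to mean 0, SD 1
#' across samples, and the first right singular vector of the standardized
#' member x sample matrix (unit norm over samples) is taken. Its sign is
#' fixed so that it correlates non-negatively with the mean standardized
#' member profile. The variance explained is the first squared singular
#' value over the total.
#'
#' @param table an [AbundanceTable-class] in relative mode.
#' @param partition a [ModulePartition-class].
#' @param module module id (must have at least one member present in the
#'   table; single-member modules are flagged).
#' @return list: module, eigengene (named numeric, one value per sample),
#'   var_explained, n_members, flag (`"ok"` or `"single_member"`).
#' @export
moduleEigengene <- function(table, partition, module) {
  stopifnot(is(table, "AbundanceTable"), is(partition, "ModulePartition"))
  if (abundanceMode(table) != "relative")
    stop("moduleEigengene() expects a table in relative mode")
  members <- names(partition@membership)[partition@membership == module]
  members <- intersect(members, rownames(table))
  if (length(members) == 0)
    stop(sprintf("module '%s' has no members in the table", module))
  X <- SummarizedExperiment::assay(table)[members, , drop = FALSE]
  Xs <- t(apply(X, 1, function(r) {
    s <- sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))

  if (length(members) == 1L) {
    v <- Xs[1, ]
    nv <- sqrt(sum(v^2))
    eg <- if (nv > 0) v / nv else v
    return(list(module = module, eigengene = setNames(eg, colnames(X)),
                var_explained = 1, n_members = 1L, flag = "single_member"))
  }

  sv <- svd(Xs)
  eg <- sv$v[, 1]
  tot <- sum(sv$d^2)
  ve <- if (tot > 0) sv$d[1]^2 / tot else NA_real_
  ref <- colMeans(Xs)
  if (sum(eg * ref) < 0) eg <- -eg
  list(module = module, eigengene = setNames(eg, colnames(X)),
       var_explained = ve, n_members = length(members), flag = "ok")
}

#' Eigengenes for all sufficiently large modules
#'
#' @param table an [AbundanceTable-class] in relative mode.
#' @param partition a [ModulePartition-class].
#' @param minSize smallest module (members present in the table) analysed;
#'   modules below this size are skipped (small modules are also dropped
#'   from network figures by convention).
#' @return named list of [moduleEigengene()] results.
#' @export
moduleEigengenes <- function(table, partition, minSize = 4) {
  mem <- partition@membership[names(partition@membership) %in%
                                rownames(table)]
  sizes <- base::table(mem)
  mods <- as.integer(names(sizes)[sizes >= minSize])
  out <- lapply(mods, function(m) moduleEigengene(table, partition, m))
  names(out) <- as.character(mods)
  out
}

#' Spearman correlations between module eigengenes and environment
#'
#' @param profiles list of eigengene profiles from [moduleEigengenes()].
#' @param env numeric matrix, samples x environmental variables.
#' @param pMax significance threshold for the `significant` flag.
#' @return data.frame: module, variable, rho, p, significant. Line-weight
#'   exports for eigengene-environment figures are proportional to `|rho|`.
#' @export
eigengeneEnvCorrelations <- function(profiles, env, pMax = 0.05) {
  env <- as.matrix(env)
  rows <- lapply(profiles, function(pr) {
    eg <- pr$eigengene
    if (is.null(names(eg)) || !all(names(eg) %in% rownames(env))) {
      if (nrow(env) != length(eg))
        stop("env rows do not match eigengene samples")
      ev <- env
    } else {
      ev <- env[names(eg), , drop = FALSE]
    }
    n <- length(eg)
    do.call(rbind, lapply(colnames(ev), function(vn) {
      rho <- suppressWarnings(cor(rank(eg), rank(ev[, vn])))
      p <- .spearmanPvalue(matrix(rho), n)[1]
      data.frame(module = pr$module, variable = vn, rho = rho, p = p,
                 significant = !is.na(p) & p < pMax,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
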