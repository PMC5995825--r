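.BACT_PHYLA <- c("Actinobacteria", "Alphaproteobacteria",
                 "Betaproteobacteria", "Gammaproteobacteria",
                 "Bacteroidetes", "Cyanobacteria", "Planctomycetes",
                 "Acidobacteria", "Chloroflexi", "Verrucomicrobia",
                 "Gemmatimonadetes", "Firmicutes")
.EUK_PHYLA <- c("Archaeplastida", "Ciliophora", "Cryptophyta",
                "Fungi", "Stramenopiles")
.ENV_VARS <- data.frame(
  variable = c("TN", "TP", "NH4", "NO2", "DOC", "pH"),
  mean = c(2.5, 0.15, 0.5, 0.05, 5, 8),
  sd = c(0.8, 0.05, 0.2, 0.02, 1.5, 0.4),
  stringsAsFactors = FALSE)

#' Configuration for the synthetic community generator
#'
#' Defines a two-zone study design with planted correlated modules: in each
#' zone, every module has a latent per-sample factor, and each member OTU's
#' log-abundance follows `loading * s_i * factor + noise` with a
#' configurable fraction of negative loadings `s_i = -1` (producing
#' co-exclusion edges). Remaining OTUs are unstructured background.
#' Proportions come from a softmax across OTUs per sample and counts from a
#' multinomial draw at fixed sequencing depth (compositional, like amplicon
#' sequencing). Defaults emulate a two-lake-zone design: 10 samples per
#' zone, a weak-structure zone (loading 0.5) and a strong-structure zone
#' (loading 0.95), depth 20000.
#'
#' @param nSamplesPerZone samples per zone (default 10).
#' @param nOtus total OTUs (default 300).
#' @param nModules number of planted modules.
#' @param moduleSizes integer vector of module sizes (default: `nModules`
#'   modules of 15% of `nOtus` each); must sum to at most `nOtus`, the
#'   remainder being background OTUs.
#' @param loadingStrength per-zone association strength of OTUs to their
#'   module factor, each in \[0, 1\]; length 1 is recycled to both zones.
#' @param envLink named list mapping module id (as character) to
#'   `list(variable =, sign =)`: that module's factor is tied to the named
#'   environmental variable (default: module 1 to TN, module 2 to TP, both
#'   positive).
#' @param sequencingDepth reads per sample and kingdom block (default
#'   20000).
#' @param noiseSd SD of the OTU-level log-abundance noise (default 0.3).
#' @param negFraction fraction of module members with negative loading
#'   (default 0.25).
#' @param baselineSd SD of the per-OTU baseline log-abundance (default
#'   0.4).
#' @param backgroundShift additive log-abundance offset of background OTUs
#'   (default 1.6): most community mass belongs to unstructured background
#'   taxa, as in real communities where network OTUs are a small minority
#'   of total reads; this also keeps the compositional denominator stable
#'   so that planted negative correlations survive the closure.
#' @param nPhyla number of bacterial phyla drawn from (max 12).
#' @param phylumModuleBias probability that a module member takes its
#'   module's home phylum rather than a uniform random one (default 0.7).
#' @param eukFraction fraction of OTUs assigned to the microeukaryote
#'   kingdom (default 0: single 16S-like amplicon).
#' @param zoneNames character(2) zone labels.
#' @param seed integer seed; per-zone sub-seeds are derived from it.
#' @return A validated config list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nSamplesPerZone = 10, nOtus = 300, nModules = 4,
                            moduleSizes = NULL,
                            loadingStrength = c(0.5, 0.95),
                            envLink = list(
                              "1" = list(variable = "TN", sign = 1),
                              "2" = list(variable = "TP", sign = 1)),
                            sequencingDepth = 20000, noiseSd = 0.3,
                            negFraction = 0.25, baselineSd = 0.4,
                            backgroundShift = 1.6, nPhyla = 8,
                            phylumModuleBias = 0.7, eukFraction = 0,
                            zoneNames = c("zoneA", "zoneB"), seed = 1) {
  if (is.null(moduleSizes))
    moduleSizes <- rep(max(2L, floor(0.15 * nOtus)), nModules)
  nModules <- length(moduleSizes)
  if (length(loadingStrength) == 1)
    loadingStrength <- rep(loadingStrength, 2)
  cfg <- list(nSamplesPerZone = as.integer(nSamplesPerZone),
              nOtus = as.integer(nOtus), nModules = as.integer(nModules),
              moduleSizes = as.integer(moduleSizes),
              loadingStrength = loadingStrength, envLink = envLink,
              sequencingDepth = as.integer(sequencingDepth),
              noiseSd = noiseSd, negFraction = negFraction,
              baselineSd = baselineSd, backgroundShift = backgroundShift,
              nPhyla = as.integer(nPhyla),
              phylumModuleBias = phylumModuleBias,
              eukFraction = eukFraction, zoneNames = zoneNames,
              seed = as.integer(seed))
  class(cfg) <- "syntheticConfig"
  .validateSyntheticConfig(cfg)
  cfg
}

.validateSyntheticConfig <- function(cfg) {
  if (cfg$sequencingDepth <= 0)
    stop("sequencingDepth must be positive")
  if (any(cfg$moduleSizes > cfg$nOtus))
    stop("a module cannot be larger than nOtus")
  if (sum(cfg$moduleSizes) > cfg$nOtus)
    stop("module sizes must sum to at most nOtus")
  if (length(cfg$loadingStrength) != 2 ||
      any(cfg$loadingStrength < 0 | cfg$loadingStrength > 1))
    stop("loadingStrength must give one value in [0, 1] per zone")
  if (cfg$noiseSd < 0) stop("noiseSd must be non-negative")
  if (cfg$baselineSd < 0) stop("baselineSd must be non-negative")
  if (cfg$negFraction < 0 || cfg$negFraction > 1)
    stop("negFraction must lie in [0, 1]")
  if (cfg$phylumModuleBias < 0 || cfg$phylumModuleBias > 1)
    stop("phylumModuleBias must lie in [0, 1]")
  if (cfg$eukFraction < 0 || cfg$eukFraction >= 1)
    stop("eukFraction must lie in [0, 1)")
  if (length(cfg$zoneNames) != 2 || anyDuplicated(cfg$zoneNames))
    stop("zoneNames must be two distinct labels")
  badLink <- !names(cfg$envLink) %in% as.character(seq_len(cfg$nModules)) |
    !vapply(cfg$envLink, function(l)
      l$variable %in% .ENV_VARS$variable && l$sign %in% c(-1, 1), TRUE)
  if (length(cfg$envLink) && any(badLink))
    stop("envLink entries must map an existing module to one of ",
         paste(.ENV_VARS$variable, collapse = ", "), " with sign +/-1")
  invisible(cfg)
}

#' Simulate a two-zone synthetic community dataset
#'
#' Generates OTU counts, taxonomy and environmental metadata with the
#' statistical structure the network pipeline assumes. Per zone and module,
#' a latent factor is drawn per sample (standard normal, decorrelated
#' across modules so distinct planted modules remain distinguishable at
#' small sample numbers), or tied to an environmental variable when
#' `envLink` maps the module to it (the
#' variable is an affine transform of the factor, leaving rank correlations
#' intact). Member OTU log-abundances are
#' `mu_i + loading * s_i * factor + Normal(0, noiseSd)`; background OTUs
#' get `mu_i + Normal(0, noiseSd)`. Within each kingdom block, per-sample
#' proportions are the softmax of log-abundances and counts are multinomial
#' at `sequencingDepth` (so each kingdom block's column sums equal the
#' depth exactly). Phylum labels follow each module's home phylum with
#' probability `phylumModuleBias`, otherwise a uniform random phylum.
#'
#' The result is bit-reproducible for a fixed config seed; zone-level
#' randomness uses sub-seeds derived from it, so zone A's data do not
#' depend on how many zones follow.
#'
#' @param config a [syntheticConfig()] object.
#' @return An [AbundanceTable-class] in counts mode. `rowData` carries the
#'   taxonomy plus the planted `truth_module` ("background" or "M1", ...);
#'   `colData` carries `zone` and the environmental variables;
#'   `metadata(x)$truth_factors` holds the per-zone sample x module factor
#'   matrices and `metadata(x)$config` the generating config.
#' @examples
#' tab <- simulateDataset(syntheticConfig(nOtus = 60,
#'   moduleSizes = c(12, 12), seed = 7))
#' tab
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  .validateSyntheticConfig(config)
  cfg <- config
  nS <- cfg$nSamplesPerZone
  nO <- cfg$nOtus

  # OTU-level structure shared across zones
  set.seed(cfg$seed)
  moduleOf <- rep("background", nO)
  idx <- 1L
  for (m in seq_len(cfg$nModules)) {
    moduleOf[idx:(idx + cfg$moduleSizes[m] - 1L)] <- paste0("M", m)
    idx <- idx + cfg$moduleSizes[m]
  }
  mu <- rnorm(nO, 0, cfg$baselineSd) +          # baseline log-abundance
    ifelse(moduleOf == "background", cfg$backgroundShift, 0)
  sgn <- ifelse(runif(nO) < cfg$negFraction, -1, 1)
  kingdom <- ifelse(runif(nO) < cfg$eukFraction,
                    "microeukaryote", "bacterioplankton")
  bactPhyla <- .BACT_PHYLA[seq_len(min(cfg$nPhyla, length(.BACT_PHYLA)))]
  homePhylum <- bactPhyla[(seq_len(cfg$nModules) - 1L) %%
                            length(bactPhyla) + 1L]
  phylum <- character(nO)
  for (i in seq_len(nO)) {
    pool <- if (kingdom[i] == "bacterioplankton") bactPhyla else .EUK_PHYLA
    m <- moduleOf[i]
    phylum[i] <- if (m != "background" &&
                     kingdom[i] == "bacterioplankton" &&
                     runif(1) < cfg$phylumModuleBias)
      homePhylum[as.integer(sub("M", "", m))]
    else sample(pool, 1)
  }
  otuIds <- sprintf("Otu%04d", seq_len(nO))

  counts <- NULL
  envAll <- NULL
  zoneOf <- character(0)
  truthFactors <- list()
  for (z in 1:2) {
    set.seed(cfg$seed + z)                      # per-zone sub-stream
    lambda <- cfg$loadingStrength[z]
    sampleIds <- sprintf("%s_S%02d", cfg$zoneNames[z], seq_len(nS))

    factors <- matrix(rnorm(nS * cfg$nModules), nS, cfg$nModules)
    if (cfg$nModules > 1 && nS > cfg$nModules) {
      # decorrelate the planted factors so the planted module structure is
      # identifiable at small sample numbers
      factors <- qr.Q(qr(factors)) * sqrt(nS - 1)
      factors <- apply(factors, 2, function(f) (f - mean(f)) / sd(f))
    }
    dimnames(factors) <- list(sampleIds, paste0("M", seq_len(cfg$nModules)))
    env <- matrix(NA_real_, nS, nrow(.ENV_VARS),
                  dimnames = list(sampleIds, .ENV_VARS$variable))
    linkedVar <- setNames(rep(NA_character_, cfg$nModules),
                          colnames(factors))
    for (mname in names(cfg$envLink)) {
      lk <- cfg$envLink[[mname]]
      linkedVar[paste0("M", mname)] <- lk$variable
      vr <- .ENV_VARS[.ENV_VARS$variable == lk$variable, ]
      env[, lk$variable] <- vr$mean +
        vr$sd * lk$sign * factors[, paste0("M", mname)]
    }
    for (v in .ENV_VARS$variable[!.ENV_VARS$variable %in%
                                   vapply(cfg$envLink, `[[`, "", "variable")]) {
      vr <- .ENV_VARS[.ENV_VARS$variable == v, ]
      env[, v] <- vr$mean + vr$sd * rnorm(nS)
    }

    logAb <- matrix(rnorm(nO * nS, 0, cfg$noiseSd), nO, nS) + mu
    for (m in seq_len(cfg$nModules)) {
      rows <- moduleOf == paste0("M", m)
      logAb[rows, ] <- logAb[rows, , drop = FALSE] +
        lambda * outer(sgn[rows], factors[, m])
    }

    zc <- matrix(0L, nO, nS, dimnames = list(otuIds, sampleIds))
    for (k in unique(kingdom)) {
      rows <- which(kingdom == k)
      for (j in seq_len(nS)) {
        la <- logAb[rows, j]
        prop <- exp(la - max(la))
        prop <- prop / sum(prop)
        zc[rows, j] <- rmultinom(1, cfg$sequencingDepth, prop)[, 1]
      }
    }
    counts <- cbind(counts, zc)
    envAll <- rbind(envAll, env)
    zoneOf <- c(zoneOf, rep(cfg$zoneNames[z], nS))
    truthFactors[[cfg$zoneNames[z]]] <- factors
  }

  taxonomy <- data.frame(
    kingdom = kingdom, phylum = phylum,
    class = "unclassified", order = "unclassified",
    family = "unclassified",
    genus = paste0("g_", phylum),
    truth_module = moduleOf,
    row.names = otuIds, stringsAsFactors = FALSE)
  sampleData <- data.frame(zone = zoneOf, envAll,
                           row.names = rownames(envAll),
                           stringsAsFactors = FALSE)
  out <- AbundanceTable(counts, taxonomy = taxonomy,
                        sampleData = sampleData, mode = "counts")
  S4Vectors::metadata(out) <- list(truth_factors = truthFactors,
                                   config = cfg)
  out
}

#' Simulate a weak-structure vs strong-structure zone contrast
#'
#' Convenience wrapper around [simulateDataset()] fixing the per-zone
#' loadings: the first zone gets `weakLoading`, the second `strongLoading`,
#' so the second zone's co-occurrence network comes out larger and denser
#' when the same pipeline is applied to both.
#'
#' @param config a [syntheticConfig()] object.
#' @param weakLoading,strongLoading loadings for zones 1 and 2.
#' @return An [AbundanceTable-class]; see [simulateDataset()].
#' @export
simulateTwoZoneDataset <- function(config, weakLoading = 0.5,
                                   strongLoading = 0.95) {
  stopifnot(inherits(config, "syntheticConfig"))
  config$loadingStrength <- c(weakLoading, strongLoading)
  .validateSyntheticConfig(config)
  simulateDataset(config)
}

#' Planted module labels of a synthetic dataset
#'
#' @param x an [AbundanceTable-class] from [simulateDataset()].
#' @return named character vector OTU -> "M1", ..., or "background".
#' @export
truthModules <- function(x) {
  tx <- taxonomy(x)
  if (!"truth_module" %in% colnames(tx))
    stop("no truth_module annotation: not a synthetic dataset?")
  setNames(tx$truth_module, rownames(tx))
}
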