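#' Pipeline configuration
#'
#' Bundles input paths, analysis thresholds and run options for
#' [runPipeline()]. Threshold defaults are the conventional values for
#' correlation-based co-occurrence analysis: Spearman `|rho| >= 0.9` with
#' `p < 0.01` and `q < 0.05` for species-species edges; `|rho| >= 0.6`
#' with `p < 0.05` for species-environment edges; prevalence of at least 8
#' samples per group; Zi/Pi role thresholds 2.5 and 0.62; modules below 4
#' members skipped in eigengene analysis.
#'
#' @param counts,taxonomy,metadata,groups input TSV paths (see
#'   [readAbundanceTable()]); alternatively pass an `AbundanceTable`
#'   directly to [runPipeline()].
#' @param outDir output directory.
#' @param rMin,pMax,qMax species-species edge thresholds.
#' @param envRMin,envPMax species-environment edge thresholds.
#' @param minPrevalence per-group prevalence filter.
#' @param ziThr,piThr node-role thresholds.
#' @param minModuleSize smallest module analysed for eigengenes.
#' @param nullModel,nReplicates random-network null model and ensemble size.
#' @param ccMode clustering convention, see [networkIndices()].
#' @param seed integer seed for all stochastic stages.
#' @return a validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(counts = NULL, taxonomy = NULL, metadata = NULL,
                           groups = NULL, outDir = "micronet-results",
                           rMin = 0.9, pMax = 0.01, qMax = 0.05,
                           envRMin = 0.6, envPMax = 0.05,
                           minPrevalence = 8, ziThr = 2.5, piThr = 0.62,
                           minModuleSize = 4,
                           nullModel = c("gnm", "degree_preserving_swap"),
                           nReplicates = 1000,
                           ccMode = c("exclude", "zero"), seed = 1) {
  nullModel <- match.arg(nullModel)
  ccMode <- match.arg(ccMode)
  stopifnot(rMin > 0, rMin <= 1, pMax > 0, pMax <= 1, qMax > 0, qMax <= 1,
            envRMin > 0, envRMin <= 1, envPMax > 0, envPMax <= 1,
            minPrevalence >= 1, ziThr > 0, piThr > 0, piThr < 1,
            minModuleSize >= 1, nReplicates >= 2)
  cfg <- list(counts = counts, taxonomy = taxonomy, metadata = metadata,
              groups = groups, outDir = outDir, rMin = rMin, pMax = pMax,
              qMax = qMax, envRMin = envRMin, envPMax = envPMax,
              minPrevalence = minPrevalence, ziThr = ziThr, piThr = piThr,
              minModuleSize = minModuleSize, nullModel = nullModel,
              nReplicates = nReplicates, ccMode = ccMode,
              seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

# Analysis for one (zone, community) table; returns results + writes files.
.runCommunity <- function(rel, cfg, tag, outDir) {
  screen <- spearmanScreen(rel)
  net <- buildNetwork(screen, rel, cfg$rMin, cfg$pMax, cfg$qMax)
  if (nrow(net@edges) == 0)
    return(list(tag = tag, n_nodes = 0, n_edges = 0, empty = TRUE))

  part <- detectModules(net)
  idx <- networkIndices(net, part, ccMode = cfg$ccMode)
  ens <- randomEnsemble(net, n = cfg$nReplicates, model = cfg$nullModel,
                        seed = cfg$seed, ccMode = cfg$ccMode)
  ztests <- do.call(rbind, lapply(c("MD", "CC", "APL", "ND"),
                                  function(i) zTest(idx[[i]], ens, i)))
  orPos <- orRatio(net, "positive", nRandom = cfg$nReplicates,
                   model = cfg$nullModel, seed = cfg$seed)
  orNeg <- orRatio(net, "negative", nRandom = cfg$nReplicates,
                   model = cfg$nullModel, seed = cfg$seed)
  roles <- classifyRoles(ziPi(net, part), cfg$ziThr, cfg$piThr)
  env <- envData(rel)
  envTab <- if (ncol(env)) envEdges(rel, env, cfg$envRMin, cfg$envPMax)
  eigs <- moduleEigengenes(rel, part, cfg$minModuleSize)
  eigCor <- if (length(eigs) && ncol(env))
    eigengeneEnvCorrelations(eigs, env, cfg$envPMax)
  fit <- if (igraph::vcount(net@graph) >= 10)
    tryCatch(fitDegreeDistribution(net), warning = function(w) NULL,
             error = function(e) NULL)

  pre <- file.path(outDir, tag)
  writeEdgeTSV(net, paste0(pre, "_edges.tsv"))
  exportGraphML(net, paste0(pre, "_network.graphml"), part)
  .writeTSV(data.frame(otu = names(part@membership),
                       module = unname(part@membership)),
            paste0(pre, "_modules.tsv"))
  .writeTSV(roles, paste0(pre, "_node_roles.tsv"))
  .writeTSV(rbind(orPos, orNeg), paste0(pre, "_or_ratio.tsv"))
  if (!is.null(envTab)) .writeTSV(envTab, paste0(pre, "_env_edges.tsv"))
  if (length(eigs)) {
    egMat <- do.call(rbind, lapply(eigs, function(e) e$eigengene))
    rownames(egMat) <- paste0("M", names(eigs))
    .writeTSV(as.data.frame(egMat), paste0(pre, "_eigengenes.tsv"),
              rowColName = "module")
  }
  if (!is.null(eigCor))
    .writeTSV(eigCor, paste0(pre, "_eigengene_env.tsv"))
  report <- list(
    indices = as.list(idx),
    null_summary = nullStats(ens),
    z_tests = ztests,
    degree_fit = if (!is.null(fit)) fit$fits,
    best_degree_model = if (!is.null(fit)) fit$best_model)
  jsonlite::write_json(report, paste0(pre, "_indices.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  list(tag = tag, network = net, partition = part, indices = idx,
       ensemble = ens, z_tests = ztests, or_ratio = rbind(orPos, orNeg),
       roles = roles, env_edges = envTab, eigengenes = eigs,
       eigengene_env = eigCor, degree_fit = fit, empty = FALSE)
}

#' Run the full co-occurrence network pipeline
#'
#' For every zone and community type (bacterioplankton, microeukaryotes,
#' and inter-kingdom when both kingdoms are present), the pipeline filters
#' OTUs by prevalence, converts to relative abundances, screens Spearman
#' correlations, builds the thresholded network, detects modules, computes
#' topological indices with random-network Z-tests, O/R co-occurrence
#' ratios, Zi-Pi node roles, environment edges and module
#' eigengene-environment correlations, writing TSV/GraphML/JSON artifacts
#' per (zone, community) plus a run manifest.
#'
#' @param config a [pipelineConfig()]; input paths may be omitted when
#'   `table` is given.
#' @param table optional [AbundanceTable-class] in counts mode (overrides
#'   the config input paths).
#' @return invisible list of per-(zone, community) results.
#' @export
runPipeline <- function(config = pipelineConfig(), table = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  t0 <- Sys.time()
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(config$outDir, "manifest.json")
  manifest <- list(
    package = "micronet",
    version = as.character(packageVersion("micronet")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[!vapply(config, is.null, TRUE)],
    status = "failed", stages = character(0))
  writeManifest <- function() {
    manifest$wall_clock_sec <<-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  on.exit(writeManifest())

  if (is.null(table)) {
    if (is.null(config$counts))
      stop("either a counts path in the config or a table is required")
    table <- readAbundanceTable(config$counts, config$taxonomy,
                                config$metadata, config$groups)
  }
  stopifnot(is(table, "AbundanceTable"))
  if (abundanceMode(table) != "counts")
    stop("runPipeline() expects a table in counts mode")

  zn <- zones(table)
  kingdoms <- unique(taxonomy(table)$kingdom)
  results <- list()
  for (z in unique(zn)) {
    perKingdom <- list()
    for (k in kingdoms) {
      ktab <- table[taxonomy(table)$kingdom == k, ]
      filtered <- prevalenceFilter(ktab, z, config$minPrevalence)
      if (nrow(filtered) < 2) next
      perKingdom[[k]] <- toRelative(filtered)
    }
    tabs <- perKingdom
    if (length(perKingdom) > 1)
      tabs[["inter_kingdom"]] <- Reduce(combineKingdoms, perKingdom)
    for (nm in names(tabs)) {
      tag <- sprintf("%s_%s", z, nm)
      manifest$stages <- c(manifest$stages, tag)
      results[[tag]] <- .runCommunity(tabs[[nm]], config, tag,
                                      config$outDir)
    }
  }
  manifest$status <- "ok"
  invisible(results)
}
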