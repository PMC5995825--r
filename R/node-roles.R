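#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For node i in module s with k_is links to nodes of module s:
#' Zi = (k_is - mean of k_js over j in s) / SD of k_js over j in s
#' (population SD by default, the original formulation), standardizing each
#' node's within-module degree against its module; Zi = 0 when the module's
#' within-degree SD is 0. Pi = 1 - sum over modules t of (k_it / k_i)^2,
#' the participation of node i's links among modules: 0 when all links stay
#' inside one module, approaching 1 - 1/M when spread evenly over M modules.
#'
#' @param network a [CoNetwork-class].
#' @param partition a [ModulePartition-class] covering all network nodes.
#' @param sdType `"population"` (default) or `"sample"`.
#' @return data.frame, one row per node: otu, module, zi, pi, degree,
#'   within_degree, kingdom, phylum, mean_abundance.
#' @export
ziPi <- function(network, partition, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  stopifnot(is(network, "CoNetwork"), is(partition, "ModulePartition"))
  g <- network@graph
  ids <- igraph::V(g)$name
  mem <- partition@membership[ids]
  if (anyNA(mem)) stop("partition does not cover all network nodes")

  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  mods <- sort(unique(mem))
  M <- matrix(0, length(ids), length(mods),
              dimnames = list(ids, as.character(mods)))
  M[cbind(seq_along(ids), match(mem, mods))] <- 1
  K <- as.matrix(A %*% M)            # K[i, s] = links of i into module s
  k <- rowSums(K)
  kin <- K[cbind(seq_along(ids), match(mem, mods))]

  zi <- numeric(length(ids))
  for (s in seq_along(mods)) {
    inMod <- mem == mods[s]
    x <- kin[inMod]
    mu <- mean(x)
    sdev <- if (sdType == "population") sqrt(mean((x - mu)^2))
            else sd(x)
    zi[inMod] <- if (is.na(sdev) || sdev == 0) 0 else (x - mu) / sdev
  }
  pi <- 1 - rowSums((K / k)^2)

  data.frame(otu = ids, module = mem, zi = zi, pi = pi,
             degree = k, within_degree = kin,
             kingdom = network@nodes[ids, "kingdom"],
             phylum = network@nodes[ids, "phylum"],
             mean_abundance = network@nodes[ids, "mean_abundance"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify node topological roles from Zi and Pi
#'
#' Applies the simplified four-role scheme with the conventional thresholds
#' Zi = 2.5 and Pi = 0.62 (boundaries inclusive on the low side):
#' peripheral (Zi <= 2.5, Pi <= 0.62), connector (Zi <= 2.5, Pi > 0.62),
#' module hub (Zi > 2.5, Pi <= 0.62), network hub (Zi > 2.5, Pi > 0.62).
#'
#' @param records data.frame from [ziPi()] (needs columns `zi`, `pi`).
#' @param ziThr,piThr classification thresholds.
#' @return the input data.frame with a `role` column.
#' @export
classifyRoles <- function(records, ziThr = 2.5, piThr = 0.62) {
  stopifnot(all(c("zi", "pi") %in% colnames(records)))
  hi_z <- records$zi > ziThr
  hi_p <- records$pi > piThr
  records$role <- ifelse(hi_z & hi_p, "network_hub",
                  ifelse(hi_z, "module_hub",
                  ifelse(hi_p, "connector", "peripheral")))
  records
}
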