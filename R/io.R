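# Tab-delimited I/O. All inputs are UTF-8 TSV with a header row; lines
# starting with '#' are ignored.

.readTSV <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read the standard input tables
#'
#' `readCountsTSV()`: counts TSV, first column the OTU id, remaining
#' columns one per sample. `readTaxonomyTSV()`: columns `otu`, `kingdom`,
#' `phylum`, `class`, `order`, `family`, `genus` (missing ranks allowed;
#' `unclassified` permitted at any rank). `readMetadataTSV()`: column
#' `sample` plus environmental variables. `readGroupsTSV()`: columns
#' `sample`, `group`.
#'
#' @param path file path.
#' @return `readCountsTSV()` a numeric matrix; the others data.frames.
#' @name tsv-input
#' @export
readCountsTSV <- function(path) {
  df <- .readTSV(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname tsv-input
#' @export
readTaxonomyTSV <- function(path) .readTSV(path)

#' @rdname tsv-input
#' @export
readMetadataTSV <- function(path) .readTSV(path)

#' @rdname tsv-input
#' @export
readGroupsTSV <- function(path) .readTSV(path)

#' Assemble an AbundanceTable from the standard input files
#'
#' @param countsPath,taxonomyPath,metadataPath,groupsPath paths to the
#'   counts, taxonomy, sample-metadata and sample-group TSVs (taxonomy,
#'   metadata and groups optional).
#' @return An [AbundanceTable-class] in counts mode.
#' @export
readAbundanceTable <- function(countsPath, taxonomyPath = NULL,
                               metadataPath = NULL, groupsPath = NULL) {
  counts <- readCountsTSV(countsPath)
  taxonomy <- if (!is.null(taxonomyPath)) readTaxonomyTSV(taxonomyPath)
  sampleData <- if (!is.null(metadataPath)) readMetadataTSV(metadataPath)
  if (!is.null(groupsPath)) {
    groups <- readGroupsTSV(groupsPath)
    zone <- data.frame(sample = groups$sample, zone = groups$group,
                       stringsAsFactors = FALSE)
    sampleData <- if (is.null(sampleData)) zone
                  else merge(zone, sampleData, by = "sample", sort = FALSE)
  }
  AbundanceTable(counts, taxonomy = taxonomy, sampleData = sampleData,
                 mode = "counts")
}

.writeTSV <- function(df, path, rowColName = NULL) {
  if (!is.null(rowColName)) {
    df <- data.frame(setNames(list(rownames(df)), rowColName),
                     as.data.frame(df), check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset as the standard input TSVs
#'
#' Writes `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `groups.tsv` and,
#' for synthetic data, `truth.tsv` (planted module per OTU) into a
#' directory.
#'
#' @param x an [AbundanceTable-class] in counts mode.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeDatasetTSV <- function(x, dir) {
  stopifnot(is(x, "AbundanceTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTSV(SummarizedExperiment::assay(x), file.path(dir, "counts.tsv"),
            rowColName = "otu")
  tx <- taxonomy(x)
  truth <- NULL
  if ("truth_module" %in% colnames(tx)) {
    truth <- data.frame(otu = rownames(tx),
                        truth_module = tx$truth_module,
                        stringsAsFactors = FALSE)
    tx$truth_module <- NULL
  }
  .writeTSV(tx, file.path(dir, "taxonomy.tsv"), rowColName = "otu")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  .writeTSV(cd[, setdiff(colnames(cd), "zone"), drop = FALSE],
            file.path(dir, "metadata.tsv"), rowColName = "sample")
  .writeTSV(data.frame(sample = colnames(x), group = unname(zones(x))),
            file.path(dir, "groups.tsv"))
  if (!is.null(truth)) .writeTSV(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Export a network as GraphML
#'
#' Writes a Cytoscape-loadable GraphML file with node attributes (kingdom,
#' phylum, mean relative abundance, and module when a partition is given)
#' and edge attributes (rho, sign, kingdom_pair).
#'
#' @param network a [CoNetwork-class].
#' @param path output file path.
#' @param partition optional [ModulePartition-class]; adds a `module` node
#'   attribute.
#' @return the path, invisibly.
#' @export
exportGraphML <- function(network, path, partition = NULL) {
  stopifnot(is(network, "CoNetwork"))
  g <- network@graph
  ids <- igraph::V(g)$name
  igraph::V(g)$kingdom <- network@nodes[ids, "kingdom"]
  igraph::V(g)$phylum <- network@nodes[ids, "phylum"]
  igraph::V(g)$mean_abundance <- network@nodes[ids, "mean_abundance"]
  if (!is.null(partition))
    igraph::V(g)$module <- unname(partition@membership[ids])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the edge table of a network as TSV
#'
#' Columns: otu_a, otu_b, rho, p, q, sign, kingdom_pair.
#'
#' @param network a [CoNetwork-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeTSV <- function(network, path) {
  stopifnot(is(network, "CoNetwork"))
  .writeTSV(network@edges, path)
}
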