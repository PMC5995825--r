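#' Filter OTUs by prevalence within a sample group
#'
#' Restricts the table to the samples of one group (zone) and keeps only
#' OTUs detected (count > 0) in at least `minPrevalence` of those samples.
#' Screening out OTUs that appear in only a few samples improves the
#' reliability of the downstream correlation network; the default of 8 out
#' of 10 samples per zone is the conventional choice for designs with ten
#' samples per group.
#'
#' @param x an [AbundanceTable-class] in counts mode.
#' @param group group (zone) label to select.
#' @param minPrevalence minimum number of samples of the group in which an
#'   OTU must be present; must not exceed the group size.
#' @return An [AbundanceTable-class] in counts mode restricted to the group's
#'   samples and the prevalent OTUs; input OTU order is preserved.
#' @examples
#' tab <- simulateDataset(syntheticConfig(nOtus = 40, moduleSizes = rep(8, 2),
#'                                        seed = 1))
#' prevalenceFilter(tab, "zoneA", minPrevalence = 8)
#' @export
setMethod("prevalenceFilter", "AbundanceTable",
  function(x, group, minPrevalence = 8) {
    if (abundanceMode(x) != "counts")
      stop("prevalenceFilter() expects a table in counts mode")
    zn <- zones(x)
    if (!group %in% zn)
      stop(sprintf("unknown group label '%s'; available: %s", group,
                   paste(unique(zn), collapse = ", ")))
    keepSamples <- names(zn)[zn == group]
    if (minPrevalence > length(keepSamples))
      stop(sprintf(
        "minPrevalence (%d) exceeds the size of group '%s' (%d samples)",
        minPrevalence, group, length(keepSamples)))
    sub <- x[, keepSamples]
    present <- rowSums(SummarizedExperiment::assay(sub) > 0)
    sub[present >= minPrevalence, ]
  })

#' Convert counts to relative abundances
#'
#' Divides each OTU count by the total count of its kingdom block in that
#' sample, so that proportions are closed per amplicon (16S and 18S are
#' sequenced separately and their depths are not comparable).
#'
#' @param x an [AbundanceTable-class] in counts mode; every sample must have
#'   a positive total within each kingdom block.
#' @return An [AbundanceTable-class] in relative mode.
#' @examples
#' counts <- matrix(c(10, 30, 60), ncol = 1,
#'                  dimnames = list(paste0("Otu", 1:3), "S1"))
#' SummarizedExperiment::assay(toRelative(AbundanceTable(counts)))
#' @export
setMethod("toRelative", "AbundanceTable", function(x) {
  if (abundanceMode(x) != "counts")
    stop("toRelative() expects a table in counts mode")
  v <- SummarizedExperiment::assay(x)
  kd <- as.character(SummarizedExperiment::rowData(x)$kingdom)
  for (k in unique(kd)) {
    rows <- kd == k
    tot <- colSums(v[rows, , drop = FALSE])
    bad <- colnames(v)[tot == 0]
    if (length(bad))
      stop(sprintf("zero total count for kingdom '%s' in sample(s): %s",
                   k, paste(bad, collapse = ", ")))
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, tot, "/")
  }
  out <- x
  SummarizedExperiment::assay(out) <- v
  out@abundanceMode <- "relative"
  validObject(out)
  out
})

#' Combine two kingdoms into one inter-kingdom table
#'
#' Row-concatenates two relative-abundance tables (e.g. bacterioplankton and
#' microeukaryotes) over the same samples. Each kingdom keeps its own closed
#' composition; downstream edge classification distinguishes intra- from
#' inter-kingdom edges via the kingdom tag.
#'
#' @param x,y [AbundanceTable-class] objects in relative mode with identical
#'   sample ids.
#' @return An [AbundanceTable-class] in relative mode with the OTUs of both
#'   inputs (x first).
#' @export
setMethod("combineKingdoms", signature("AbundanceTable", "AbundanceTable"),
  function(x, y) {
    if (abundanceMode(x) != "relative" || abundanceMode(y) != "relative")
      stop("combineKingdoms() expects both tables in relative mode")
    if (nrow(y) == 0L) return(x)
    if (nrow(x) == 0L) return(y)
    diff <- c(setdiff(colnames(x), colnames(y)),
              setdiff(colnames(y), colnames(x)))
    if (length(diff))
      stop("sample ids differ between tables: ",
           paste(unique(diff), collapse = ", "))
    y <- y[, colnames(x)]
    dup <- intersect(rownames(x), rownames(y))
    if (length(dup))
      stop("duplicated OTU ids across kingdoms: ",
           paste(utils::head(dup, 5), collapse = ", "))
    ranks <- union(colnames(taxonomy(x)), colnames(taxonomy(y)))
    fill <- function(tab) {
      tx <- taxonomy(tab)
      for (r in setdiff(ranks, colnames(tx))) tx[[r]] <- "unclassified"
      tx[, ranks, drop = FALSE]
    }
    values <- rbind(SummarizedExperiment::assay(x),
                    SummarizedExperiment::assay(y))
    AbundanceTable(values,
                   taxonomy = rbind(fill(x), fill(y)),
                   sampleData = as.data.frame(
                     SummarizedExperiment::colData(x)),
                   mode = "relative")
  })
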