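#' Construct an AbundanceTable
#'
#' @param values numeric matrix, OTUs x samples (counts or proportions).
#' @param taxonomy data.frame of taxonomic ranks keyed by OTU id (rownames or
#'   an `otu` column). Missing ranks are filled with `"unclassified"`; a
#'   missing `kingdom` column defaults to `"bacterioplankton"`.
#' @param sampleData data.frame keyed by sample id (rownames or a `sample`
#'   column) with the group label (`zone`) and environmental variables.
#' @param mode `"counts"` or `"relative"`.
#'
#' @return An [AbundanceTable-class] object.
#' @examples
#' counts <- matrix(rpois(30, 50), nrow = 5,
#'                  dimnames = list(paste0("Otu", 1:5), paste0("S", 1:6)))
#' tab <- AbundanceTable(counts)
#' abundanceMode(tab)
#' @export
AbundanceTable <- function(values, taxonomy = NULL, sampleData = NULL,
                           mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("'values' must have OTU ids as rownames")
  if (is.null(colnames(values)))
    stop("'values' must have sample ids as colnames")

  taxonomy <- .normalizeKeyedFrame(taxonomy, rownames(values), "otu", "OTU")
  if (!"kingdom" %in% colnames(taxonomy))
    taxonomy$kingdom <- "bacterioplankton"
  for (rank in c("phylum", "class", "order", "family", "genus"))
    if (!rank %in% colnames(taxonomy)) taxonomy[[rank]] <- "unclassified"
  taxonomy[] <- lapply(taxonomy, function(col) {
    col <- as.character(col)
    col[is.na(col) | col == ""] <- "unclassified"
    col
  })

  sampleData <- .normalizeKeyedFrame(sampleData, colnames(values),
                                     "sample", "sample")
  if (!"zone" %in% colnames(sampleData)) sampleData$zone <- "all"

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    rowData = S4Vectors::DataFrame(taxonomy),
    colData = S4Vectors::DataFrame(sampleData))
  new("AbundanceTable", se, abundanceMode = mode)
}

# Align a keyed data.frame (rownames or an id column) to the given ids.
.normalizeKeyedFrame <- function(df, ids, idCol, what) {
  if (is.null(df)) return(data.frame(row.names = ids))
  df <- as.data.frame(df)
  if (idCol %in% colnames(df)) {
    rownames(df) <- as.character(df[[idCol]])
    df[[idCol]] <- NULL
  }
  missing <- setdiff(ids, rownames(df))
  if (length(missing))
    stop(sprintf("%s ids missing from annotation: %s", what,
                 paste(utils::head(missing, 5), collapse = ", ")))
  df[ids, , drop = FALSE]
}

#' @rdname AbundanceTable
#' @export
setMethod("abundanceMode", "AbundanceTable", function(x) x@abundanceMode)

#' @rdname AbundanceTable
#' @export
setMethod("taxonomy", "AbundanceTable", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname AbundanceTable
#' @export
setMethod("zones", "AbundanceTable", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$zone), colnames(x)))

#' @rdname AbundanceTable
#' @export
setMethod("envData", "AbundanceTable", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  num <- vapply(cd, is.numeric, logical(1))
  as.matrix(cd[, num, drop = FALSE])
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable (%s mode): %d OTUs x %d samples\n",
              object@abundanceMode, nrow(object), ncol(object)))
  kd <- table(taxonomy(object)$kingdom)
  cat("kingdoms:", paste(sprintf("%s (%d)", names(kd), kd), collapse = ", "),
      "\n")
  zn <- table(zones(object))
  cat("zones:", paste(sprintf("%s (%d)", names(zn), zn), collapse = ", "),
      "\n")
})

#' Phylum labels with optional Proteobacteria class split
#'
#' Returns the phylum of each OTU, optionally replacing `Proteobacteria`
#' with the class (Alphaproteobacteria, Betaproteobacteria, ...), the
#' phylum/subphylum resolution commonly used for co-occurrence tables of
#' freshwater bacterioplankton.
#'
#' @param x an [AbundanceTable-class], or a taxonomy data.frame.
#' @param splitProteobacteria replace Proteobacteria by its class label
#'   where the class is known.
#' @return named character vector of phylum (or subphylum) labels.
#' @export
phylumLabels <- function(x, splitProteobacteria = TRUE) {
  tax <- if (is(x, "AbundanceTable")) SummarizedExperiment::rowData(x)
         else x
  phy <- as.character(tax$phylum)
  if (splitProteobacteria && "class" %in% colnames(tax)) {
    cls <- as.character(tax$class)
    sub <- phy == "Proteobacteria" & !is.na(cls) & cls != "unclassified"
    phy[sub] <- cls[sub]
  }
  phy[is.na(phy) | phy == ""] <- "unclassified"
  names(phy) <- rownames(tax)
  phy
}
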