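#' @rdname AbundanceTable
#' @param x,object an object.
#' @export
setGeneric("abundanceMode", function(x) standardGeneric("abundanceMode"))

#' @rdname AbundanceTable
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname AbundanceTable
#' @export
setGeneric("zones", function(x) standardGeneric("zones"))

#' @rdname AbundanceTable
#' @export
setGeneric("envData", function(x) standardGeneric("envData"))

#' @rdname prevalenceFilter
#' @export
setGeneric("prevalenceFilter",
  function(x, group, minPrevalence = 8) standardGeneric("prevalenceFilter"))

#' @rdname toRelative
#' @export
setGeneric("toRelative", function(x) standardGeneric("toRelative"))

#' @rdname combineKingdoms
#' @export
setGeneric("combineKingdoms",
  function(x, y) standardGeneric("combineKingdoms"))

#' @rdname spearmanScreen
#' @export
setGeneric("spearmanScreen",
  function(x, pMethod = c("t", "exact"), qMethod = c("storey", "BH"))
    standardGeneric("spearmanScreen"))

#' @rdname CoNetwork-accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname CoNetwork-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname CoNetwork-accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname detectModules
#' @export
setGeneric("detectModules", function(x) standardGeneric("detectModules"))

#' @rdname ModulePartition-accessors
#' @export
setGeneric("moduleMembership",
  function(x) standardGeneric("moduleMembership"))

#' @rdname ModulePartition-accessors
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname ModulePartition-accessors
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname NullEnsembleSummary-accessors
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))

#' @rdname NullEnsembleSummary-accessors
#' @export
setGeneric("nullReplicates", function(x) standardGeneric("nullReplicates"))
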