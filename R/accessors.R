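## Accessors and show methods.

#' @describeIn CompoundSet-class number of compounds
#' @param x,object a CompoundSet
#' @export
setMethod("length", "CompoundSet", function(x) length(x@ids))

#' Compound identifiers
#' @param x a CompoundSet or AnalogSeries
#' @return character vector of ids
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@ids)

#' Target labels of the configured potency fields
#' @param x a CompoundSet
#' @export
setGeneric("targetLabels", function(x) standardGeneric("targetLabels"))

#' @rdname targetLabels
#' @export
setMethod("targetLabels", "CompoundSet", function(x) x@targets)

#' Potency matrix (compounds x targets)
#' @param x a CompoundSet
#' @export
setGeneric("potencies", function(x) standardGeneric("potencies"))

#' @rdname potencies
#' @export
setMethod("potencies", "CompoundSet", function(x) {
  m <- x@potencies
  dimnames(m) <- list(x@ids, x@targets)
  m
})

#' Look up one compound's molecular graph by id
#' @keywords internal
getCompound <- function(cs, id) {
  i <- match(id, cs@ids)
  if (is.na(i)) stop("unknown compound id: ", id)
  cs@compounds[[i]]
}

#' Series identifier
#' @param x an AnalogSeries
#' @export
setGeneric("seriesId", function(x) standardGeneric("seriesId"))

#' @rdname seriesId
#' @export
setMethod("seriesId", "AnalogSeries", function(x) x@seriesId)

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "AnalogSeries", function(x) x@memberIds)

#' Series core structure
#' @param x an AnalogSeries
#' @export
setGeneric("seriesCore", function(x) standardGeneric("seriesCore"))

#' @rdname seriesCore
#' @export
setMethod("seriesCore", "AnalogSeries", function(x) x@core)

#' Number of indexed substitution sites
#' @param x a CoreStructure or SubsetPartition
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname nSites
#' @export
setMethod("nSites", "CoreStructure", function(x) x@nSites)

#' @rdname nSites
#' @export
setMethod("nSites", "SubsetPartition", function(x) x@nSites)

#' Core canonical SMILES (constitution level)
#' @param x a CoreStructure
#' @export
setGeneric("coreSmiles", function(x) standardGeneric("coreSmiles"))

#' @rdname coreSmiles
#' @export
setMethod("coreSmiles", "CoreStructure", function(x) x@smiles)

#' Node and edge tables of a SAR graph
#' @param x a SarGraph
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "SarGraph", function(x) x@nodes)

#' @rdname graphNodes
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphNodes
#' @export
setMethod("graphEdges", "SarGraph", function(x) x@edges)

#' Node table of an R-group tree
#' @param x an RGroupTree
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname treeNodes
#' @export
setMethod("treeNodes", "RGroupTree", function(x) x@nodes)

#' Subset membership table of a partition
#' @param x a SubsetPartition
#' @return data.frame with columns label, compoundId
#' @export
setGeneric("subsetMembers", function(x) standardGeneric("subsetMembers"))

#' @rdname subsetMembers
#' @export
setMethod("subsetMembers", "SubsetPartition", function(x) {
  data.frame(label = rep(x@labels, lengths(x@members)),
             compoundId = unlist(x@members, use.names = FALSE),
             stringsAsFactors = FALSE)
})

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet with", length(object@ids), "compounds,",
      length(object@targets), "potency field(s):",
      paste(object@targets, collapse = ", "), "\n")
})

setMethod("show", "AnalogSeries", function(object) {
  cat("AnalogSeries", object@seriesId, "-", length(object@memberIds),
      "members, scaffold:", object@scaffoldSmiles, "\n")
  if (is(object@core, "CoreStructure"))
    cat("  core:", object@core@smiles, "with", object@core@nSites, "sites\n")
})

setMethod("show", "CoreStructure", function(object) {
  cat("CoreStructure:", object@smiles, "(", object@graph$n, "atoms,",
      nrow(object@graph$bonds), "bonds,", object@nSites, "sites )\n")
  if (object@lowCoverage) cat("  flagged: low coverage\n")
  if (object@timedOut) cat("  flagged: MCS timeout, scaffold used\n")
})

setMethod("show", "SubsetPartition", function(object) {
  cat("SubsetPartition of", object@seriesId, "-", length(object@labels),
      "subsets over", sum(lengths(object@members)), "compounds\n")
})

setMethod("show", "SarGraph", function(object) {
  cat("SarGraph (", object@kind, ") for", object@seriesId, "-",
      nrow(object@nodes), "nodes,", nrow(object@edges), "edges\n")
})

setMethod("show", "RGroupTree", function(object) {
  nd <- object@nodes
  cat("RGroupTree for subset", object@subsetLabel, "-",
      sum(nd$type == "leaf"), "leaves, layer order:",
      paste(object@layerOrder, collapse = " "), "\n")
})
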