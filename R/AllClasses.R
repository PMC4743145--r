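#' @import methods
NULL

#' CompoundSet: molecules with potency annotations
#'
#' Container for the compounds read from one SD file. Each compound holds its
#' heavy-atom molecular graph (with stereo parsed from wedge bonds and 2D
#' coordinates), the raw molfile block for lossless re-export, and a named
#' vector of potency values (negative-log scale, e.g. pKi or pIC50).
#'
#' @slot compounds list of internal molecular-graph records, one per compound.
#' @slot ids character vector of unique compound identifiers.
#' @slot targets character vector of target labels for the potency columns.
#' @slot potencies numeric matrix, compounds x targets (NA = not measured).
#' @slot source character, path of the SD file the set was read from.
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(compounds = "list", ids = "character",
                 targets = "character", potencies = "matrix",
                 source = "character"))

setValidity("CompoundSet", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "compound ids must be unique")
  if (length(object@compounds) != length(object@ids))
    msgs <- c(msgs, "one molecular graph per id required")
  if (nrow(object@potencies) != length(object@ids))
    msgs <- c(msgs, "potency matrix must have one row per compound")
  p <- object@potencies
  if (length(p) && any(is.infinite(p) | is.nan(p)))
    msgs <- c(msgs, "potency values must be finite or NA")
  if (length(msgs)) msgs else TRUE
})

#' AnalogSeries: a scaffold-defined group of analogs
#'
#' @slot seriesId character identifier (assigned deterministically).
#' @slot scaffoldSmiles canonical SMILES of the shared scaffold
#'   (NA for a merged series whose members stem from different scaffolds).
#' @slot scaffoldLevel "framework" or "generic_skeleton".
#' @slot memberIds character vector of member compound ids.
#' @slot core the series [CoreStructure-class] (empty until computed).
#' @exportClass AnalogSeries
setClass("AnalogSeries",
  representation(seriesId = "character", scaffoldSmiles = "character",
                 scaffoldLevel = "character", memberIds = "character",
                 core = "ANY"))

setValidity("AnalogSeries", function(object) {
  if (anyDuplicated(object@memberIds)) "duplicate member ids" else TRUE
})

#' CoreStructure: the series MCS with indexed substitution sites
#'
#' Core atoms are numbered canonically (independent of input order); the
#' substitution sites R1..Rn are the core atoms carrying a non-hydrogen
#' substituent in at least one member, numbered by canonical atom rank.
#'
#' @slot graph internal graph of the core (elements, charges, bonds with
#'   Kekule order, match order and ring flags inherited from the molecule the
#'   MCS was extracted from).
#' @slot smiles constitution-level canonical SMILES of the core.
#' @slot siteAtoms integer vector: core atom index of site k at position k.
#' @slot nSites integer.
#' @slot lowCoverage TRUE when the MCS fell below the configured minimum
#'   fraction of the mean heavy-atom count.
#' @slot timedOut TRUE when the MCS search hit its time ceiling and the
#'   scaffold was used as core instead.
#' @exportClass CoreStructure
setClass("CoreStructure",
  representation(graph = "list", smiles = "character", siteAtoms = "integer",
                 nSites = "integer", lowCoverage = "logical",
                 timedOut = "logical"))

setValidity("CoreStructure", function(object) {
  msgs <- character(0)
  if (object@nSites != length(object@siteAtoms))
    msgs <- c(msgs, "nSites must equal length(siteAtoms)")
  if (anyDuplicated(object@siteAtoms))
    msgs <- c(msgs, "each core atom can carry at most one site number")
  if (length(msgs)) msgs else TRUE
})

#' SubsetPartition: disjoint site-combination subsets of a series
#'
#' @slot seriesId character.
#' @slot combinations list of sorted integer vectors (one per subset; the
#'   empty combination is the root "0").
#' @slot labels character labels parallel to `combinations`.
#' @slot members list of character vectors of compound ids, parallel to
#'   `combinations`.
#' @slot nSites integer, number of substitution sites of the series core.
#' @exportClass SubsetPartition
setClass("SubsetPartition",
  representation(seriesId = "character", combinations = "list",
                 labels = "character", members = "list", nSites = "integer"))

setValidity("SubsetPartition", function(object) {
  msgs <- character(0)
  if (length(object@combinations) != length(object@members) ||
      length(object@labels) != length(object@members))
    msgs <- c(msgs, "combinations, labels and members must be parallel")
  all <- unlist(object@members)
  if (anyDuplicated(all))
    msgs <- c(msgs, "subsets must be pairwise disjoint")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "subset labels must be unique")
  if (length(msgs)) msgs else TRUE
})

#' SarGraph: layered DAG over substitution-site combinations
#'
#' Nodes are site combinations with per-subset statistics; directed edges run
#' from a combination to the combinations one layer below that extend it by
#' exactly one site.
#'
#' @slot kind "complete" or "reduced".
#' @slot nodes data.frame with columns label, layer, count, meanPotency,
#'   potencyRange, empty, x (layout hint), and optionally potencyDiff for
#'   selectivity views.
#' @slot edges data.frame with columns from, to (node labels).
#' @slot seriesId character.
#' @slot target character, the potency target the statistics refer to.
#' @exportClass SarGraph
setClass("SarGraph",
  representation(kind = "character", nodes = "data.frame",
                 edges = "data.frame", seriesId = "character",
                 target = "character"))

setValidity("SarGraph", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("complete", "reduced"))
    msgs <- c(msgs, "kind must be 'complete' or 'reduced'")
  nd <- object@nodes
  if (nrow(nd)) {
    if (anyDuplicated(nd$label)) msgs <- c(msgs, "node labels must be unique")
    bad <- nd$empty != (nd$count == 0)
    if (any(bad)) msgs <- c(msgs, "empty flag must mirror count == 0")
    if (any(!is.na(nd$potencyRange) & nd$potencyRange < 0))
      msgs <- c(msgs, "potency ranges must be non-negative")
  }
  ed <- object@edges
  if (nrow(ed)) {
    lay <- stats::setNames(nd$layer, nd$label)
    if (any(lay[ed$to] - lay[ed$from] != 1))
      msgs <- c(msgs, "every edge must cross exactly one layer")
  }
  if (length(msgs)) msgs else TRUE
})

#' RGroupTree: per-subset tree resolving analogs and stereoisomers
#'
#' @slot subsetLabel character label of the site combination.
#' @slot layerOrder integer vector: the subset's sites in tree-layer order
#'   (ascending number of distinct R-groups).
#' @slot nodes data.frame with columns id, parent (NA for root), depth, type
#'   ("root", "group", "leaf"), site, rgroup, count, meanPotency, compoundId,
#'   potency, stereoIndex.
#' @slot seriesId character.
#' @exportClass RGroupTree
setClass("RGroupTree",
  representation(subsetLabel = "character", layerOrder = "integer",
                 nodes = "data.frame", seriesId = "character"))

setValidity("RGroupTree", function(object) {
  nd <- object@nodes
  if (!nrow(nd)) return("tree must have at least a root")
  msgs <- character(0)
  if (sum(is.na(nd$parent)) != 1) msgs <- c(msgs, "exactly one root required")
  leaves <- nd[nd$type == "leaf", ]
  if (anyDuplicated(leaves$compoundId))
    msgs <- c(msgs, "each compound may appear in exactly one leaf")
  si <- leaves$stereoIndex[!is.na(leaves$stereoIndex)]
  if (length(si) && any(table(si) < 2))
    msgs <- c(msgs, "stereo-group indices require >= 2 members")
  if (length(msgs)) msgs else TRUE
})

#' FixtureSpec: recipe for a synthetic analog series
#'
#' @slot coreTemplate SMILES with `{R1}`..`{Rn}` placeholders at the
#'   substitution positions.
#' @slot substituentPools named list (site -> data.frame with columns smiles,
#'   effect); "H" as smiles means the site stays unsubstituted.
#' @slot occupancyPattern list of integer vectors: the site combination each
#'   generated compound realizes (one compound per entry).
#' @slot stereoPattern named list: compound index (as character) -> number of
#'   stereoisomer variants to emit for that realization.
#' @slot basePotency numeric, potency of the bare core (log units).
#' @slot noiseSd numeric, s.d. of the seeded Gaussian noise (log units).
#' @slot potencyFields character, SD tag name(s) to write.
#' @slot targetEffects named numeric offsets per extra potency field (for
#'   selectivity fixtures).
#' @slot seed integer.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(coreTemplate = "character", substituentPools = "list",
                 occupancyPattern = "list", stereoPattern = "list",
                 basePotency = "numeric", noiseSd = "numeric",
                 potencyFields = "character", targetEffects = "numeric",
                 seed = "integer"))

setValidity("FixtureSpec", function(object) {
  msgs <- character(0)
  nSites <- length(object@substituentPools)
  used <- unique(unlist(object@occupancyPattern))
  if (length(used) && max(used) > nSites)
    msgs <- c(msgs, "occupancy pattern refers to a site without a pool")
  if (!length(object@potencyFields))
    msgs <- c(msgs, "at least one potency field required")
  if (length(msgs)) msgs else TRUE
})
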