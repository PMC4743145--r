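## R-group trees: per-subset hierarchical view of substituents.
##
## Layers are the subset's sites ordered by ascending number of distinct
## R-groups (most conserved site nearest the root; ties by site number).
## Children split their parent's compounds by the R-group at the layer's
## site, ordered lexicographically by R-group SMILES; the final grouping
## leaves one leaf per compound, stereoisomers (identical constitution)
## adjacent.

#' Build the R-group tree of one subset
#'
#' @param analysis a [SeriesAnalysis-class].
#' @param label subset label (see [combinationLabel()]).
#' @param target potency target (default: first configured).
#' @return an [RGroupTree-class]
#' @export
buildRGroupTree <- function(analysis, label, target = NULL) {
  part <- analysis@partition
  k <- match(label, part@labels)
  if (is.na(k)) stop("no subset with label '", label, "' in this series")
  ids <- part@members[[k]]
  sites <- part@combinations[[k]]
  cs <- analysis@compounds
  target <- .resolveTarget(cs, target)
  pots <- stats::setNames(potencies(cs)[, target], rownames(potencies(cs)))
  asg <- analysis@assignments

  rgroupAt <- function(id, site) asg[[id]]$groups[[as.character(site)]]
  nUnique <- vapply(sites, function(s)
    length(unique(vapply(ids, rgroupAt, character(1), site = s))), integer(1))
  layerOrder <- sites[order(nUnique, sites)]

  nodes <- data.frame(id = integer(0), parent = integer(0), depth = integer(0),
                      type = character(0), site = integer(0),
                      rgroup = character(0), count = integer(0),
                      meanPotency = numeric(0), compoundId = character(0),
                      potency = numeric(0), stereoIndex = integer(0),
                      stringsAsFactors = FALSE)
  addNode <- function(parent, depth, type, site = NA_integer_,
                      rgroup = NA_character_, count = NA_integer_,
                      meanPotency = NA_real_, compoundId = NA_character_,
                      potency = NA_real_) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, parent, depth, type, site, rgroup, count,
                         meanPotency, compoundId, potency, NA_integer_)
    id
  }

  root <- addNode(NA_integer_, 0L, "root", count = length(ids),
                  meanPotency = mean(pots[ids]))
  grow <- function(parent, depth, members) {
    if (depth > length(layerOrder)) {
      ## leaves: stereoisomers (same constitution) adjacent, ids sorted
      key <- vapply(members, function(id) asg[[id]]$constitution, character(1))
      for (id in members[order(key, members)])
        addNode(parent, depth, "leaf", compoundId = id, potency = pots[id])
      return(invisible())
    }
    site <- layerOrder[depth]
    gr <- vapply(members, rgroupAt, character(1), site = site)
    for (g in sort(unique(gr))) {
      sel <- members[gr == g]
      nd <- addNode(parent, depth, "group", site = site, rgroup = g,
                    count = length(sel), meanPotency = mean(pots[sel]))
      grow(nd, depth + 1L, sel)
    }
    invisible()
  }
  grow(root, 1L, sort(ids))

  tree <- new("RGroupTree", subsetLabel = label,
              layerOrder = as.integer(layerOrder), nodes = nodes,
              seriesId = part@seriesId)
  assignStereoIndices(tree, analysis)
}

#' Assign stereo-group indices to the leaves of an R-group tree
#'
#' Constitution classes with two or more leaves are stereoisomer sets; they
#' receive incremental indices 1, 2, ... in left-to-right tree order, and all
#' leaves of one class carry the class index. Singleton leaves carry none.
#'
#' @param tree an [RGroupTree-class].
#' @param analysis the [SeriesAnalysis-class] providing constitutions.
#' @return the tree with the `stereoIndex` column filled in.
#' @export
assignStereoIndices <- function(tree, analysis) {
  nodes <- tree@nodes
  leaf <- which(nodes$type == "leaf")       # row order = left-to-right order
  if (!length(leaf)) return(tree)
  const <- vapply(nodes$compoundId[leaf], function(id)
    analysis@assignments[[id]]$constitution, character(1))
  counts <- table(const)
  nextIdx <- 1L
  assigned <- c()
  for (i in seq_along(leaf)) {
    cl <- const[i]
    if (counts[[cl]] < 2L) next
    if (is.null(assigned[cl]) || is.na(assigned[cl])) {
      assigned[cl] <- nextIdx
      nextIdx <- nextIdx + 1L
    }
    nodes$stereoIndex[leaf[i]] <- assigned[cl]
  }
  tree@nodes <- nodes
  validObject(tree)
  tree
}

#' Stereo-group indices of one subset
#'
#' @param analysis a [SeriesAnalysis-class].
#' @param label subset label.
#' @return named integer vector (compound id -> index; NA when the compound
#'   is not part of a stereoisomer set).
#' @keywords internal
subsetStereoIndices <- function(analysis, label) {
  tree <- buildRGroupTree(analysis, label)
  nd <- tree@nodes[tree@nodes$type == "leaf", ]
  stats::setNames(nd$stereoIndex, nd$compoundId)
}
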