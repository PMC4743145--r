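## Subset partition and layered SAR graphs.
##
## Every compound belongs to exactly one subset: the exact set of its
## substituted sites. The complete graph spans all 2^n site combinations
## (root "0" = the hypothetical bare core); the reduced graph is the induced
## subgraph on non-empty nodes, with no transitive re-wiring across removed
## nodes.

#' Label of a site combination
#'
#' Concatenated site digits ("0" for the empty combination); dot-separated
#' when any site number has two digits, keeping the encoding bijective.
#' @param sites sorted integer vector (possibly empty).
#' @export
combinationLabel <- function(sites) {
  if (!length(sites)) return("0")
  sites <- sort(sites)
  if (max(sites) >= 10) paste(sites, collapse = ".")
  else paste(sites, collapse = "")
}

#' Parse a combination label back into site numbers
#' @param label a label produced by [combinationLabel()].
#' @export
parseCombinationLabel <- function(label) {
  if (label == "0") return(integer(0))
  if (grepl(".", label, fixed = TRUE))
    as.integer(strsplit(label, ".", fixed = TRUE)[[1]])
  else as.integer(strsplit(label, "")[[1]])
}

#' Deterministic display order of combinations (layer, then site numbers)
#' @keywords internal
orderCombinations <- function(combos) {
  keys <- vapply(combos, function(s)
    paste0(sprintf("%02d", length(s)), "|",
           paste(sprintf("%02d", s), collapse = ",")), character(1))
  order(keys)
}

#' Partition a series into site-combination subsets
#'
#' @param series an [AnalogSeries-class] with an indexed core.
#' @param assignments named list from [decomposeRGroups()] (one entry per
#'   member).
#' @return a [SubsetPartition-class]
#' @export
partitionSeries <- function(series, assignments) {
  core <- series@core
  missing <- setdiff(series@memberIds, names(assignments))
  if (length(missing))
    stop("members lack an R-group assignment: ",
         paste(missing, collapse = ", "))
  byLabel <- list(); combos <- list()
  for (id in series@memberIds) {
    sites <- sort(assignments[[id]]$nonH)
    lab <- combinationLabel(sites)
    if (is.null(byLabel[[lab]])) combos[[lab]] <- as.integer(sites)
    byLabel[[lab]] <- c(byLabel[[lab]], id)
  }
  labs <- names(byLabel)
  ord <- orderCombinations(combos[labs])
  part <- new("SubsetPartition", seriesId = series@seriesId,
              combinations = unname(combos[labs][ord]),
              labels = labs[ord],
              members = unname(byLabel[ord]),
              nSites = core@nSites)
  validObject(part)
  part
}

#' Per-node subset statistics
#'
#' @param compoundIds compound ids in the subset (possibly empty).
#' @param pots named numeric potency vector for the chosen target.
#' @return list(count, meanPotency, potencyRange); mean and range are NA for
#'   an empty subset, range = max - min in log units (orders of magnitude).
#' @export
nodeStatistics <- function(compoundIds, pots) {
  if (!length(compoundIds))
    return(list(count = 0L, meanPotency = NA_real_, potencyRange = NA_real_))
  v <- pots[compoundIds]
  if (anyNA(v))
    stop("missing potency for: ",
         paste(compoundIds[is.na(v)], collapse = ", "))
  list(count = length(v), meanPotency = mean(v),
       potencyRange = max(v) - min(v))
}

.allCombinations <- function(n) {
  out <- list(integer(0))
  for (k in seq_len(n))
    out <- c(out, utils::combn(n, k, simplify = FALSE))
  out
}

.sarNodes <- function(combos, part, pots) {
  byLabel <- stats::setNames(part@members, part@labels)
  labs <- vapply(combos, combinationLabel, character(1))
  nodes <- data.frame(label = labs,
                      layer = lengths(combos),
                      count = 0L, meanPotency = NA_real_,
                      potencyRange = NA_real_, empty = TRUE, x = 0,
                      stringsAsFactors = FALSE)
  for (i in seq_along(combos)) {
    ids <- byLabel[[labs[i]]]
    st <- nodeStatistics(if (is.null(ids)) character(0) else ids, pots)
    nodes$count[i] <- st$count
    nodes$meanPotency[i] <- st$meanPotency
    nodes$potencyRange[i] <- st$potencyRange
    nodes$empty[i] <- st$count == 0L
  }
  ## layout hint: position within layer, in combination order
  for (l in unique(nodes$layer)) {
    sel <- which(nodes$layer == l)
    nodes$x[sel] <- seq_along(sel)
  }
  nodes
}

.adjacentEdges <- function(combos) {
  labs <- vapply(combos, combinationLabel, character(1))
  from <- character(0); to <- character(0)
  byLayer <- split(seq_along(combos), lengths(combos))
  for (l in names(byLayer)) {
    l2 <- as.character(as.integer(l) + 1L)
    if (is.null(byLayer[[l2]])) next
    for (i in byLayer[[l]]) for (j in byLayer[[l2]]) {
      if (all(combos[[i]] %in% combos[[j]])) {
        from <- c(from, labs[i]); to <- c(to, labs[j])
      }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Build the complete graph of a series
#'
#' All 2^n site combinations (including the root "0") in layers 0..n; edges
#' connect adjacent-layer subset pairs.
#'
#' @param part a [SubsetPartition-class].
#' @param cs the [CompoundSet-class].
#' @param target target label (default: first configured target).
#' @param maxSites refuse the exponential node set beyond this many sites
#'   (default 12); use [buildReducedGraphDirect()] instead.
#' @return a [SarGraph-class] of kind "complete".
#' @export
buildCompleteGraph <- function(part, cs, target = NULL, maxSites = 12L) {
  n <- part@nSites
  if (n < 1L) stop("complete graph requires at least one substitution site")
  if (n > maxSites)
    stop("complete graph over ", n, " sites would have ", 2^n, " nodes; ",
         "build the reduced graph directly (buildReducedGraphDirect)")
  target <- .resolveTarget(cs, target)
  pots <- stats::setNames(potencies(cs)[, target], rownames(potencies(cs)))
  combos <- .allCombinations(n)
  g <- new("SarGraph", kind = "complete",
           nodes = .sarNodes(combos, part, pots),
           edges = .adjacentEdges(combos),
           seriesId = part@seriesId, target = target)
  validObject(g)
  g
}

.resolveTarget <- function(cs, target) {
  labels <- unname(cs@targets)
  if (is.null(target)) return(labels[1])
  if (!target %in% labels)
    stop("unknown target '", target, "'; configured: ",
         paste(labels, collapse = ", "))
  target
}

#' Reduce a complete graph
#'
#' Removes every empty node together with its edges (plain induced subgraph:
#' no transitive edges are added across removed nodes, so reduced graphs may
#' be disconnected).
#'
#' @param graph a [SarGraph-class].
#' @return a [SarGraph-class] of kind "reduced".
#' @export
reduceGraph <- function(graph) {
  keep <- graph@nodes$label[!graph@nodes$empty]
  nodes <- graph@nodes[!graph@nodes$empty, , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- graph@edges[graph@edges$from %in% keep &
                       graph@edges$to %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  g <- new("SarGraph", kind = "reduced", nodes = nodes, edges = edges,
           seriesId = graph@seriesId, target = graph@target)
  validObject(g)
  g
}

#' Build a reduced graph directly from the occupied combinations
#'
#' Equivalent to `reduceGraph(buildCompleteGraph(...))` but never
#' materializes the 2^n node set; intended for series with many sites.
#'
#' @inheritParams buildCompleteGraph
#' @export
buildReducedGraphDirect <- function(part, cs, target = NULL) {
  target <- .resolveTarget(cs, target)
  pots <- stats::setNames(potencies(cs)[, target], rownames(potencies(cs)))
  combos <- part@combinations
  g <- new("SarGraph", kind = "reduced",
           nodes = .sarNodes(combos, part, pots),
           edges = .adjacentEdges(combos),
           seriesId = part@seriesId, target = target)
  validObject(g)
  g
}

#' Target-by-target selectivity views of one series
#'
#' Members lacking a potency for either target are dropped (with a warning)
#' before partitioning, so both reduced graphs share one partition and one
#' topology; only the node statistics differ. Each node additionally carries
#' `potencyDiff` = meanPotency(targetA) - meanPotency(targetB).
#'
#' @param analysis a [SeriesAnalysis-class].
#' @param targetA,targetB the two target labels.
#' @return list of two [SarGraph-class] objects named by target.
#' @export
buildSelectivityViews <- function(analysis, targetA, targetB) {
  cs <- analysis@compounds
  labels <- unname(cs@targets)
  if (length(labels) < 2L)
    stop("selectivity analysis requires at least 2 configured potency fields")
  targetA <- .resolveTarget(cs, targetA)
  targetB <- .resolveTarget(cs, targetB)
  pm <- potencies(cs)
  series <- analysis@series
  ok <- series@memberIds[!is.na(pm[series@memberIds, targetA]) &
                         !is.na(pm[series@memberIds, targetB])]
  dropped <- setdiff(series@memberIds, ok)
  if (length(dropped))
    warning(length(dropped), " member(s) lack potency for one target and ",
            "were dropped from the selectivity view", call. = FALSE)
  sub <- series
  sub@memberIds <- ok
  part <- partitionSeries(sub, analysis@assignments[ok])
  gA <- buildReducedGraphDirect(part, cs, targetA)
  gB <- buildReducedGraphDirect(part, cs, targetB)
  diff <- gA@nodes$meanPotency - gB@nodes$meanPotency
  gA@nodes$potencyDiff <- diff
  gB@nodes$potencyDiff <- diff
  stats::setNames(list(gA, gB), c(targetA, targetB))
}
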