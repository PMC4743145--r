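## Symmetry-consistent mapping of compounds onto the series core,
## substitution-site indexing and R-group decomposition.
##
## A symmetric core admits many embeddings into each member; the canonical
## one is chosen by minimizing, in order, (a) the sorted list of occupied
## site positions (core atoms are canonically numbered, so this is
## input-order independent), (b) the per-site substituent SMILES, (c) the
## mapped compound-atom index sequence. Under this rule all mono-substituted
## members of a symmetric core occupy the same site.

.coreBonds <- function(core) core@graph$bonds[, c("a", "b", "morder", "ringb")]

.occupiedCoreAtoms <- function(mg, map, nbrs = molNeighbors(mg)) {
  inImage <- logical(mg$n); inImage[map] <- TRUE
  which(vapply(seq_along(map), function(k) {
    any(!inImage[nbrs[[map[k]]]])
  }, logical(1)))
}

.outsideFragments <- function(mg, map) {
  outside <- setdiff(seq_len(mg$n), map)
  if (!length(outside)) return(list())
  onOut <- mg$bonds$a %in% outside & mg$bonds$b %in% outside
  g <- igraph::make_graph(
    edges = rbind(match(mg$bonds$a[onOut], outside),
                  match(mg$bonds$b[onOut], outside)),
    n = length(outside), directed = FALSE)
  memb <- igraph::components(g)$membership
  lapply(sort(unique(memb)), function(ci) outside[memb == ci])
}

.fragmentInfo <- function(mg, map, fragAtoms) {
  ## bonds linking the fragment to the core image
  inFrag <- logical(mg$n); inFrag[fragAtoms] <- TRUE
  inImage <- logical(mg$n); inImage[map] <- TRUE
  att <- which((inFrag[mg$bonds$a] & inImage[mg$bonds$b]) |
               (inFrag[mg$bonds$b] & inImage[mg$bonds$a]))
  coreAtoms <- vapply(att, function(i) {
    cmpdAtom <- if (inImage[mg$bonds$a[i]]) mg$bonds$a[i] else mg$bonds$b[i]
    match(cmpdAtom, map)
  }, integer(1))
  fragEnds <- vapply(att, function(i) {
    if (inFrag[mg$bonds$a[i]]) mg$bonds$a[i] else mg$bonds$b[i]
  }, integer(1))
  list(attachBonds = att, coreAtoms = coreAtoms, fragEnds = fragEnds,
       orders = mg$bonds$order[att])
}

.fragmentSmiles <- function(mg, fragAtoms, info) {
  sub <- subMolgraph(mg, fragAtoms)
  smi <- subgraphSmiles(sub, attachTo = match(info$fragEnds, fragAtoms),
                        attachOrder = info$orders)
  if (is.na(smi)) "~" else smi
}

.mapScoreA <- function(mg, map, nbrs) {
  occ <- .occupiedCoreAtoms(mg, map, nbrs)
  paste(sprintf("%04d", occ), collapse = "|")
}

.mapScoreB <- function(mg, map) {
  frags <- .outsideFragments(mg, map)
  bySite <- list()
  for (fa in frags) {
    info <- .fragmentInfo(mg, map, fa)
    site <- min(info$coreAtoms)
    smi <- .fragmentSmiles(mg, fa, info)
    key <- as.character(site)
    bySite[[key]] <- sort(c(bySite[[key]], smi))
  }
  sites <- sort(as.integer(names(bySite)))
  paste(vapply(sites, function(s)
    paste0(sprintf("%04d", s), "=",
           paste(bySite[[as.character(s)]], collapse = ".")), character(1)),
    collapse = "|")
}

#' Map a compound onto the series core
#'
#' Enumerates every substructure embedding of the core into the compound
#' (automorphic alternatives included) and returns the canonical one.
#'
#' @param mg a compound's molecular graph.
#' @param core a [CoreStructure-class].
#' @return integer vector: compound atom index per core atom.
#' @export
mapToCore <- function(mg, core) {
  maps <- allEmbeddings(core@graph$elem, .coreBonds(core), targetPrep(mg))
  if (!length(maps))
    stop("core is not a substructure of compound '", mg$title,
         "' (series bookkeeping error)")
  if (length(maps) == 1L) return(maps[[1]])
  nbrs <- molNeighbors(mg)
  a <- vapply(maps, function(m) .mapScoreA(mg, m, nbrs), character(1))
  maps <- maps[a == min(a)]
  if (length(maps) > 1L) {
    b <- vapply(maps, function(m) .mapScoreB(mg, m), character(1))
    maps <- maps[b == min(b)]
  }
  if (length(maps) > 1L) {
    cc <- vapply(maps, function(m) paste(sprintf("%05d", m), collapse = ""),
                 character(1))
    maps <- maps[order(cc)]
  }
  maps[[1]]
}

#' Index the substitution sites of a core
#'
#' Sites are the core atoms carrying a non-hydrogen substituent in at least
#' one member, numbered 1..n by canonical atom rank of the core.
#'
#' @param core a [CoreStructure-class].
#' @param mappings named list (compound id -> mapping from [mapToCore()]).
#' @param cs the [CompoundSet-class].
#' @return the core with `siteAtoms`/`nSites` filled in.
#' @export
indexSubstitutionSites <- function(core, mappings, cs) {
  occ <- integer(0)
  for (id in names(mappings)) {
    mg <- getCompound(cs, id)
    occ <- union(occ, .occupiedCoreAtoms(mg, mappings[[id]]))
  }
  core@siteAtoms <- sort(occ)
  core@nSites <- length(occ)
  validObject(core)
  core
}

#' Decompose one compound into per-site R-groups
#'
#' @param mg compound molecular graph.
#' @param core indexed [CoreStructure-class].
#' @param map canonical mapping from [mapToCore()].
#' @return list with `compoundId`, `groups` (character named by site number;
#'   canonical stereo-free SMILES with `*` attachment markers, "H" when
#'   unsubstituted, multiple fragments at one site joined by "."), `bridged`
#'   (named logical: fragment attached to more than one core atom), and
#'   `nonH` (integer site numbers carrying a substituent).
#' @export
decomposeRGroups <- function(mg, core, map) {
  n <- core@nSites
  groups <- stats::setNames(rep("H", n), as.character(seq_len(n)))
  bridged <- stats::setNames(rep(FALSE, n), as.character(seq_len(n)))
  frags <- .outsideFragments(mg, map)
  for (fa in frags) {
    info <- .fragmentInfo(mg, map, fa)
    if (!length(info$coreAtoms))
      stop("non-core atoms of '", mg$title,
           "' not attached to the mapped core (integrity error)")
    siteNums <- sort(unique(match(info$coreAtoms, core@siteAtoms)))
    if (anyNA(siteNums))
      stop("substituent of '", mg$title,
           "' attached at an unindexed core position (integrity error)")
    site <- as.character(min(siteNums))
    smi <- .fragmentSmiles(mg, fa, info)
    groups[site] <- if (groups[site] == "H") smi
                    else paste(sort(c(strsplit(groups[site], ".",
                                               fixed = TRUE)[[1]], smi)),
                               collapse = ".")
    if (length(unique(info$coreAtoms)) > 1L) bridged[site] <- TRUE
  }
  list(compoundId = mg$title, groups = groups, bridged = bridged,
       nonH = unname(which(groups != "H")))
}

#' Reassemble a compound's constitution from core + R-groups
#'
#' Builds a molecule from the core graph and the fragment SMILES of every
#' non-H group, reattaching each fragment at its site, and returns the
#' constitution-level canonical SMILES. Used to verify that decomposition is
#' lossless (bridged assignments are not reassembled; returns NA).
#'
#' @param core indexed [CoreStructure-class].
#' @param assignment result of [decomposeRGroups()].
#' @return canonical SMILES string or NA.
#' @export
reassembleConstitution <- function(core, assignment) {
  if (any(assignment$bridged)) return(NA_character_)
  elem <- core@graph$elem
  charge <- core@graph$charge
  bonds <- core@graph$bonds[, c("a", "b", "morder")]
  names(bonds)[3] <- "order"
  for (siteChr in names(assignment$groups)) {
    g <- assignment$groups[[siteChr]]
    if (g == "H") next
    siteAtom <- core@siteAtoms[as.integer(siteChr)]
    for (smi in strsplit(g, ".", fixed = TRUE)[[1]]) {
      sdfTxt <- obConvert("SMI", "SDF", smi)
      rec <- strsplit(sdfTxt, "\n", fixed = TRUE)[[1]]
      frag <- .parseOneRecord(rec, 1L)
      if (is.null(frag)) return(NA_character_)
      off <- length(elem)
      dummies <- which(frag$elem == "*")
      elem <- c(elem, frag$elem)
      charge <- c(charge, frag$charge)
      fb <- frag$bonds
      keep <- !(fb$a %in% dummies | fb$b %in% dummies)
      bonds <- rbind(bonds, data.frame(a = fb$a[keep] + off,
                                       b = fb$b[keep] + off,
                                       order = ifelse(frag$arom[keep], 1.5,
                                                      fb$order[keep])))
      for (d in dummies) {
        db <- which(fb$a == d | fb$b == d)
        for (i in db) {
          nbr <- if (fb$a[i] == d) fb$b[i] else fb$a[i]
          bonds <- rbind(bonds, data.frame(a = siteAtom, b = nbr + off,
                                           order = fb$order[i]))
        }
      }
      ## drop dummy atom rows by marking them; rebuild at the end
      elem[off + dummies] <- NA_character_
    }
  }
  keepA <- which(!is.na(elem))
  idxMap <- integer(length(elem)); idxMap[keepA] <- seq_along(keepA)
  keepB <- !is.na(elem[bonds$a]) & !is.na(elem[bonds$b])
  bonds <- bonds[keepB, , drop = FALSE]
  bonds$a <- idxMap[bonds$a]; bonds$b <- idxMap[bonds$b]
  mb <- writeMolblock(elem[keepA], charge[keepA], numeric(length(keepA)),
                      numeric(length(keepA)), bonds)
  canonicalSmiles(mb, stereo = FALSE)
}

#' Merge two analog series
#'
#' The member union forms a new series whose core must be recomputed with
#' [computeMCS()] (typically via [analyzeSeries()]); all downstream
#' structures are rebuilt from the new core.
#'
#' @param a,b [AnalogSeries-class] objects.
#' @return an [AnalogSeries-class] with the union of members and no core.
#' @export
combineSeries <- function(a, b) {
  members <- sort(union(a@memberIds, b@memberIds))
  sameScaffold <- identical(a@scaffoldSmiles, b@scaffoldSmiles)
  new("AnalogSeries",
      seriesId = if (identical(a@seriesId, b@seriesId)) a@seriesId
                 else paste0(a@seriesId, "+", b@seriesId),
      scaffoldSmiles = if (sameScaffold) a@scaffoldSmiles else NA_character_,
      scaffoldLevel = a@scaffoldLevel, memberIds = members, core = NULL)
}

#' SeriesAnalysis: everything derived from one series
#'
#' @slot series the [AnalogSeries-class] (core filled in).
#' @slot core indexed [CoreStructure-class].
#' @slot mappings named list of canonical core-to-compound mappings.
#' @slot assignments named list of R-group assignments incl. stereo
#'   signatures and constitution SMILES.
#' @slot partition the [SubsetPartition-class].
#' @slot compounds the [CompoundSet-class] (reference).
#' @exportClass SeriesAnalysis
setClass("SeriesAnalysis",
  representation(series = "ANY", core = "ANY", mappings = "list",
                 assignments = "list", partition = "ANY",
                 compounds = "ANY"))

setMethod("show", "SeriesAnalysis", function(object) {
  cat("SeriesAnalysis of", object@series@seriesId, "-",
      length(object@mappings), "members,", object@core@nSites, "sites,",
      length(object@partition@labels), "subsets\n")
})

#' Run the full per-series pipeline
#'
#' Computes the MCS, maps every member onto it, indexes the substitution
#' sites, decomposes R-groups, perceives stereo signatures and partitions the
#' series into site-combination subsets.
#'
#' @param series an [AnalogSeries-class].
#' @param cs the [CompoundSet-class].
#' @param ... passed to [computeMCS()].
#' @return a [SeriesAnalysis-class]
#' @examples
#' sdf <- tempfile(fileext = ".sdf")
#' generateSeriesSDF(defaultFixtureSpec(), sdf)
#' cs <- readCompounds(sdf, "pKi")
#' ser <- groupIntoSeries(cs)[[1]]
#' an <- analyzeSeries(ser, cs)
#' an
#' @export
analyzeSeries <- function(series, cs, ...) {
  core <- computeMCS(series, cs, ...)
  ids <- series@memberIds
  mappings <- stats::setNames(
    lapply(ids, function(id) mapToCore(getCompound(cs, id), core)), ids)
  core <- indexSubstitutionSites(core, mappings, cs)
  assignments <- stats::setNames(lapply(ids, function(id) {
    mg <- getCompound(cs, id)
    asg <- decomposeRGroups(mg, core, mappings[[id]])
    asg$constitution <- mg$constitution
    asg$signature <- stereoSignature(mg)
    asg
  }), ids)
  series@core <- core
  part <- partitionSeries(series, assignments)
  new("SeriesAnalysis", series = series, core = core, mappings = mappings,
      assignments = assignments, partition = part, compounds = cs)
}
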