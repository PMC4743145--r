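## Maximum common substructure over all members of an analog series.
##
## The MCS flavor is: connected; atoms match by element; bonds match by
## order, with aromatic bonds treated as their own order so Kekule
## assignments in input files cannot split a match; ring bonds match only
## ring bonds. Among maximal solutions the tie-break is (more atoms, more
## bonds, scaffold containment preferred, lexicographically smallest
## canonical SMILES).
##
## Search: exact branch-and-bound enumeration of connected edge subgraphs of
## the member with the fewest bonds. Each subgraph is visited once
## (include/exclude recursion per boundary edge); a branch is cut when the
## current subgraph no longer embeds in some member (embedding failures are
## monotone under edge addition) or when the atoms reachable through allowed
## edges cannot strictly beat the incumbent. A greedy seed (grown from the
## series scaffold when it embeds in every member) supplies a near-optimal
## incumbent so the exact phase prunes hard.

.patBonds <- function(mg, bondIdx) {
  b <- mg$bonds[bondIdx, c("a", "b"), drop = FALSE]
  b$morder <- mg$morder[bondIdx]
  b$ringb <- mg$ringb[bondIdx]
  b
}

.embedsAllBonds <- function(ref, bondIdx, preps) {
  atoms <- sort(unique(c(ref$bonds$a[bondIdx], ref$bonds$b[bondIdx])))
  idxMap <- integer(ref$n); idxMap[atoms] <- seq_along(atoms)
  pb <- .patBonds(ref, bondIdx)
  pb$a <- idxMap[pb$a]; pb$b <- idxMap[pb$b]
  elem <- ref$elem[atoms]
  for (p in preps) if (!embedsIn(elem, pb, p)) return(FALSE)
  TRUE
}

.scaffoldPattern <- function(mg) {
  atoms <- .scaffoldAtoms(mg)
  if (length(atoms) < 2L) return(NULL)
  sub <- subMolgraph(mg, atoms)
  list(elem = sub$elem,
       bonds = sub$bonds[, c("a", "b", "morder", "ringb")],
       srcAtoms = atoms, srcBonds = sub$srcBonds)
}

#' Compute the series maximum common substructure
#'
#' @param series an [AnalogSeries-class] with at least 2 members.
#' @param cs the [CompoundSet-class] the members belong to.
#' @param minCoverageFrac flag the series as low-coverage when the MCS has
#'   fewer atoms than this fraction of the mean heavy-atom count (default
#'   2/3).
#' @param timeoutSec ceiling for the exact search (default 60 s); on timeout
#'   the series scaffold is used as core and the result is flagged.
#' @return a [CoreStructure-class] (substitution sites not yet indexed; see
#'   [indexSubstitutionSites()]).
#' @export
computeMCS <- function(series, cs, minCoverageFrac = 2/3, timeoutSec = 60) {
  ids <- series@memberIds
  if (length(ids) < 2L) stop("MCS requires a series with >= 2 members")
  mols <- lapply(ids, function(id) getCompound(cs, id))
  key <- vapply(mols, function(m)
    sprintf("%06d|%06d|%s", nrow(m$bonds), m$n, m$constitution %||% ""),
    character(1))
  refI <- order(key)[1]
  ref <- mols[[refI]]
  preps <- lapply(mols[-refI], targetPrep)
  meanHeavy <- mean(vapply(mols, function(m) m$n, numeric(1)))
  deadline <- Sys.time() + timeoutSec

  nb <- nrow(ref$bonds)
  result <- NULL
  if (nb > 0L) {
    ## canonical bond order for input-order independence
    rk <- canonicalRanks(ref)
    bkey <- sprintf("%04d|%04d|%04.1f",
                    pmin(rk[ref$bonds$a], rk[ref$bonds$b]),
                    pmax(rk[ref$bonds$a], rk[ref$bonds$b]), ref$morder)
    bondOrd <- order(bkey)
    ## bond adjacency (shared atom)
    adj <- lapply(seq_len(nb), function(i) {
      a <- ref$bonds$a[i]; b <- ref$bonds$b[i]
      setdiff(which(ref$bonds$a %in% c(a, b) | ref$bonds$b %in% c(a, b)), i)
    })
    atomsOf <- function(S) unique(c(ref$bonds$a[S], ref$bonds$b[S]))

    ## greedy seed, preferring a scaffold-anchored start
    seedVal <- c(0L, 0L)
    seed <- integer(0)
    sp <- .scaffoldPattern(ref)
    if (!is.null(sp)) {
      S0 <- sp$srcBonds
      if (.embedsAllBonds(ref, S0, preps)) seed <- S0
    }
    if (!length(seed)) {
      for (i in bondOrd) if (.embedsAllBonds(ref, i, preps)) { seed <- i; break }
    }
    if (length(seed)) {
      repeat {
        front <- setdiff(unique(unlist(adj[seed])), seed)
        front <- front[order(match(front, bondOrd))]
        grew <- FALSE
        for (e in front) {
          if (.embedsAllBonds(ref, c(seed, e), preps)) {
            seed <- c(seed, e); grew <- TRUE; break
          }
        }
        if (!grew || Sys.time() > deadline) break
      }
      seedVal <- c(length(atomsOf(seed)), length(seed))
    }

    best <- seedVal
    solutions <- list()
    nodeCount <- 0L
    timedOut <- FALSE

    record <- function(S) {
      v <- c(length(atomsOf(S)), length(S))
      if (v[1] > best[1] || (v[1] == best[1] && v[2] > best[2])) {
        best <<- v; solutions <<- list(S)
      } else if (v[1] == best[1] && v[2] == best[2] &&
                 length(solutions) < 64L) {
        solutions[[length(solutions) + 1L]] <<- S
      }
    }

    rec <- function(S, ext, forb) {
      nodeCount <<- nodeCount + 1L
      if (nodeCount %% 128L == 0L && Sys.time() > deadline) {
        timedOut <<- TRUE; return(invisible())
      }
      if (timedOut) return(invisible())
      record(S)
      if (!length(ext)) return(invisible())
      ## reachability bound
      reach <- S
      frontier <- ext
      while (length(frontier)) {
        reach <- c(reach, frontier)
        nxt <- setdiff(unique(unlist(adj[frontier])), c(reach, which(forb)))
        frontier <- nxt
      }
      potAtoms <- length(atomsOf(reach))
      potBonds <- length(reach)
      if (potAtoms < best[1] ||
          (potAtoms == best[1] && potBonds < best[2])) return(invisible())
      e <- ext[1]
      S2 <- c(S, e)
      if (.embedsAllBonds(ref, S2, preps)) {
        ext2 <- c(ext[-1], setdiff(adj[[e]], c(S2, ext, which(forb))))
        rec(S2, ext2, forb)
      }
      forb2 <- forb; forb2[e] <- TRUE
      rec(S, ext[-1], forb2)
      invisible()
    }

    forb <- logical(nb)
    for (i in bondOrd) {
      if (timedOut) break
      if (.embedsAllBonds(ref, i, preps))
        rec(i, setdiff(adj[[i]], which(forb)), forb)
      forb[i] <- TRUE
    }

    if (timedOut) {
      warning("MCS search for ", series@seriesId,
              " hit its time ceiling; falling back to the series scaffold",
              call. = FALSE)
      if (!is.null(sp) && .embedsAllBonds(ref, sp$srcBonds, preps))
        solutions <- list(sp$srcBonds)
      else if (!length(solutions) && length(seed)) solutions <- list(seed)
    }
    if (!length(solutions) && length(seed)) solutions <- list(seed)

    if (length(solutions)) {
      ## tie-break: scaffold containment, then canonical SMILES
      scPat <- sp
      keyOf <- function(S) {
        sub <- subMolgraph(ref, sort(atomsOf(S)), S)
        smi <- subgraphSmiles(sub)
        contains <- if (is.null(scPat)) FALSE else {
          prep <- .matchPrep(sub$elem,
                             sub$bonds[, c("a", "b", "morder", "ringb")])
          embedsIn(scPat$elem, scPat$bonds, prep)
        }
        list(contains = contains, smi = if (is.na(smi)) "~" else smi)
      }
      keys <- lapply(solutions, keyOf)
      ord <- order(!vapply(keys, `[[`, logical(1), "contains"),
                   vapply(keys, `[[`, character(1), "smi"))
      S <- solutions[[ord[1]]]
      result <- list(ref = ref, atoms = sort(atomsOf(S)), bonds = S,
                     timedOut = timedOut)
    }
  }

  if (is.null(result)) {
    ## no common bond: single-atom MCS on the most senior shared element
    shared <- Reduce(intersect, lapply(mols, function(m) unique(m$elem)))
    if (length(shared)) {
      el <- sort(shared)[1]
      atom <- which(ref$elem == el)[1]
      result <- list(ref = ref, atoms = atom, bonds = integer(0),
                     timedOut = FALSE)
    } else {
      warning("series ", series@seriesId, " has an empty MCS", call. = FALSE)
      core <- new("CoreStructure",
                  graph = list(n = 0L, elem = character(0),
                               charge = integer(0),
                               bonds = data.frame(a = integer(0),
                                                  b = integer(0),
                                                  order = numeric(0),
                                                  morder = numeric(0),
                                                  ringb = logical(0))),
                  smiles = NA_character_, siteAtoms = integer(0),
                  nSites = 0L, lowCoverage = TRUE, timedOut = FALSE)
      return(core)
    }
  }

  core <- .buildCore(result$ref, result$atoms, result$bonds, result$timedOut)
  if (core@graph$n < minCoverageFrac * meanHeavy) {
    core@lowCoverage <- TRUE
    warning("MCS of ", series@seriesId, " covers only ", core@graph$n,
            " of on average ", round(meanHeavy, 1),
            " heavy atoms (low coverage)", call. = FALSE)
  }
  core
}

.buildCore <- function(ref, atoms, bondIdx, timedOut = FALSE) {
  sub <- subMolgraph(ref, atoms, bondIdx)
  rk <- canonicalRanks(sub)
  perm <- order(rk)              # new index k holds the atom of rank k
  idxMap <- integer(sub$n); idxMap[perm] <- seq_along(perm)
  bonds <- sub$bonds
  bonds$a <- idxMap[bonds$a]; bonds$b <- idxMap[bonds$b]
  swap <- bonds$a > bonds$b
  tmp <- bonds$a[swap]; bonds$a[swap] <- bonds$b[swap]; bonds$b[swap] <- tmp
  bonds <- bonds[order(bonds$a, bonds$b), , drop = FALSE]
  rownames(bonds) <- NULL
  graph <- list(n = sub$n, elem = sub$elem[perm], charge = sub$charge[perm],
                bonds = bonds)
  smi <- subgraphSmiles(graph)
  new("CoreStructure", graph = graph,
      smiles = if (is.na(smi)) "~" else smi, siteAtoms = integer(0),
      nSites = 0L, lowCoverage = FALSE, timedOut = timedOut)
}
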