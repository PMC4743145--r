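## Analog-series extraction via hierarchical molecular scaffolds.
##
## The framework level follows the Bemis-Murcko convention: ring atoms, the
## linker atoms connecting rings, and atoms double-bonded to either. The
## generic skeleton additionally replaces every atom by carbon and every bond
## by a single bond, so series that differ only by heteroatom exchange or
## bond-order pattern collapse onto one skeleton.

.NO_SCAFFOLD <- "<acyclic>"

.scaffoldAtoms <- function(mg) {
  if (!any(mg$ringa)) return(integer(0))
  keep <- rep(TRUE, mg$n)
  nbrs <- molNeighbors(mg)
  ## iteratively prune terminal non-ring atoms -> rings plus linkers remain
  repeat {
    deg <- vapply(seq_len(mg$n), function(i) sum(keep[nbrs[[i]]]), integer(1))
    drop <- which(keep & !mg$ringa & deg <= 1L)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  ## re-attach atoms double-bonded to the framework (e.g. exocyclic =O)
  for (i in seq_len(nrow(mg$bonds))) {
    if (mg$bonds$order[i] == 2) {
      a <- mg$bonds$a[i]; b <- mg$bonds$b[i]
      if (keep[a] && !keep[b]) keep[b] <- TRUE
      if (keep[b] && !keep[a]) keep[a] <- TRUE
    }
  }
  which(keep)
}

#' Extract the hierarchical scaffold of a compound
#'
#' @param mg internal molecular graph of one compound (an element of a
#'   [CompoundSet-class]).
#' @param level "framework" (Bemis-Murcko) or "generic_skeleton"
#'   (carbon-only, single bonds).
#' @return list with `smiles` (canonical, stereo-free; the sentinel
#'   `"<acyclic>"` for ring-free molecules) and `atoms` (framework atom
#'   indices in the compound).
#' @export
extractScaffold <- function(mg, level = c("framework", "generic_skeleton")) {
  level <- match.arg(level)
  atoms <- .scaffoldAtoms(mg)
  if (!length(atoms))
    return(list(smiles = .NO_SCAFFOLD, atoms = integer(0), level = level))
  sub <- subMolgraph(mg, atoms)
  if (level == "generic_skeleton") {
    sub$elem <- rep("C", sub$n)
    sub$charge <- rep(0L, sub$n)
    sub$bonds$order <- rep(1L, nrow(sub$bonds))
    sub$bonds$morder <- rep(1, nrow(sub$bonds))
  }
  smi <- subgraphSmiles(sub)
  list(smiles = smi, atoms = atoms, level = level)
}

#' Group compounds into analog series by shared scaffold
#'
#' Compounds are partitioned by equal scaffold SMILES at the chosen level.
#' Groups smaller than `minSeriesSize` are left unassigned (reported via the
#' `unassigned` attribute); acyclic compounds have no scaffold and are never
#' assigned. Series ids are deterministic: sorted by member count
#' (descending), then scaffold SMILES.
#'
#' @param cs a [CompoundSet-class].
#' @param level scaffold level, see [extractScaffold()].
#' @param minSeriesSize minimum number of members (default 2; an MCS over a
#'   single compound is not meaningful).
#' @return list of [AnalogSeries-class]; attribute "unassigned" holds the
#'   ids left out.
#' @export
groupIntoSeries <- function(cs, level = c("framework", "generic_skeleton"),
                            minSeriesSize = 2L) {
  level <- match.arg(level)
  if (!length(cs@ids)) {
    out <- list(); attr(out, "unassigned") <- character(0); return(out)
  }
  scas <- vapply(cs@compounds, function(m) extractScaffold(m, level)$smiles,
                 character(1))
  ok <- scas != .NO_SCAFFOLD & !is.na(scas)
  if (any(!ok))
    message(sum(!ok), " acyclic compound(s) excluded from series formation")
  groups <- split(cs@ids[ok], scas[ok])
  big <- groups[lengths(groups) >= minSeriesSize]
  ord <- order(-lengths(big), names(big))
  big <- big[ord]
  series <- vector("list", length(big))
  for (i in seq_along(big)) {
    series[[i]] <- new("AnalogSeries", seriesId = sprintf("S%d", i),
                       scaffoldSmiles = names(big)[i], scaffoldLevel = level,
                       memberIds = sort(big[[i]]), core = NULL)
  }
  unassigned <- sort(c(cs@ids[!ok],
                       unlist(groups[lengths(groups) < minSeriesSize],
                              use.names = FALSE)))
  if (length(unassigned))
    message(length(unassigned), " compound(s) unassigned ",
            "(acyclic or group below minimum series size)")
  attr(series, "unassigned") <- unassigned
  series
}
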