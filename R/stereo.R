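## Stereo perception: CIP-style descriptors from 2D coordinates and wedges.
##
## Priorities follow CIP rule 1a (atomic number, hierarchical digraph with
## duplicated atoms for multiple bonds, implicit hydrogens included); the
## mass and stereo-descriptor refinement rules are not applied, which is
## sufficient to resolve the substituent chemistry the package targets.
## Tetrahedral centers are read from wedge bonds plus 2D coordinates,
## double-bond geometry from 2D coordinates; centers with no stereo
## annotation are reported as "?" (unspecified).

.cipExpand <- function(mg, nbrs, frontier) {
  ## frontier: list of nodes; real node = c(atom, parent); phantom = number
  out <- list()
  for (nd in frontier) {
    if (length(nd) == 1L) next                       # phantom: no children
    at <- nd[1]; par <- nd[2]
    for (x in nbrs[[at]]) {
      if (x == par) {
        ## multiple bond back to parent contributes phantom duplicates
        o <- .bondOrderBetween(mg, at, x)
        if (o > 1) for (k in seq_len(o - 1))
          out[[length(out) + 1L]] <- elementNumber(mg$elem[x])
        next
      }
      out[[length(out) + 1L]] <- c(x, at)
      o <- .bondOrderBetween(mg, at, x)
      if (o > 1) for (k in seq_len(o - 1))
        out[[length(out) + 1L]] <- elementNumber(mg$elem[x])
    }
    if (mg$hyd[at] > 0) for (k in seq_len(mg$hyd[at]))
      out[[length(out) + 1L]] <- 1
  }
  out
}

.bondOrderBetween <- function(mg, a, b) {
  i <- which((mg$bonds$a == a & mg$bonds$b == b) |
             (mg$bonds$a == b & mg$bonds$b == a))[1]
  o <- mg$bonds$order[i]
  if (o == 4) 2L else as.integer(o)   # molfile aromatic: treat as double
}

.frontierNums <- function(mg, frontier) {
  sort(vapply(frontier, function(nd)
    if (length(nd) == 1L) nd else elementNumber(mg$elem[nd[1]]),
    numeric(1)), decreasing = TRUE)
}

#' Compare the CIP priority of two branches from a common root
#'
#' @return -1, 0 or 1 (branch via `a` lower / tied / higher than via `b`).
#' @keywords internal
cipCompareBranches <- function(mg, root, a, b, maxDepth = 12L) {
  nbrs <- molNeighbors(mg)
  fa <- list(c(a, root)); fb <- list(c(b, root))
  for (d in seq_len(maxDepth)) {
    na <- .frontierNums(mg, fa); nb <- .frontierNums(mg, fb)
    L <- max(length(na), length(nb))
    if (L) {
      na <- c(na, rep(0, L - length(na))); nb <- c(nb, rep(0, L - length(nb)))
      for (i in seq_len(L)) {
        if (na[i] > nb[i]) return(1L)
        if (na[i] < nb[i]) return(-1L)
      }
    }
    fa <- .cipExpand(mg, nbrs, fa); fb <- .cipExpand(mg, nbrs, fb)
    if (!length(fa) && !length(fb)) return(0L)
  }
  0L
}

## implicit-H pseudo-branch always has priority of a lone hydrogen
.cipRankNeighbors <- function(mg, center, nbAtoms, withH) {
  items <- c(as.list(nbAtoms), if (withH) list("H"))
  n <- length(items)
  gt <- function(i, j) {
    xi <- items[[i]]; xj <- items[[j]]
    if (identical(xi, "H") && identical(xj, "H")) return(0L)
    if (identical(xi, "H")) return(-.cipVsH(mg, center, xj))
    if (identical(xj, "H")) return(.cipVsH(mg, center, xi))
    cipCompareBranches(mg, center, xi, xj)
  }
  cmp <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) cmp[i, j] <- gt(i, j)
  score <- rowSums(cmp == 1L)
  if (any(duplicated(score))) return(NULL)           # tied branches
  order(-score)                                      # priority 1 first
}

.cipVsH <- function(mg, center, atom) {
  ## any heavy branch outranks H unless it is itself H (suppressed: none)
  if (elementNumber(mg$elem[atom]) > 1) 1L else 0L
}

.tetrahedralCandidates <- function(mg, nbrs) {
  which(vapply(seq_len(mg$n), function(i) {
    if (!mg$elem[i] %in% c("C", "Si", "N", "P", "S")) return(FALSE)
    deg <- length(nbrs[[i]])
    if (deg + mg$hyd[i] != 4L || mg$hyd[i] > 1L) return(FALSE)
    inc <- mg$bonds$order[mg$bonds$a == i | mg$bonds$b == i]
    all(inc == 1)
  }, logical(1)))
}

.parityFromGeometry <- function(mg, center, nbAtoms, prio, withH) {
  ## 3D-ish coordinates: wedge endpoints leave the plane
  pos <- function(at) {
    z <- 0
    wb <- which(mg$bonds$a == center & mg$bonds$b == at & mg$bonds$wedge %in% c(1L, 6L))
    if (length(wb)) z <- if (mg$bonds$wedge[wb[1]] == 1L) 1 else -1
    c(mg$x[at], mg$y[at], z)
  }
  pts <- lapply(nbAtoms, pos)
  anyWedge <- any(vapply(pts, function(p) p[3] != 0, logical(1)))
  hx <- NULL
  if (withH) {
    hz <- -sum(vapply(pts, function(p) p[3], numeric(1)))
    ctr <- c(mg$x[center], mg$y[center])
    cen <- colMeans(do.call(rbind, lapply(pts, function(p) p[1:2])))
    hx <- c(ctr + (ctr - cen), hz)
    ## explicit suppressed H with wedge information
    hrec <- mg$hexp[[center]]
    if (!is.null(hrec) && nrow(hrec) >= 1) {
      w <- hrec[1, 3]
      hx <- c(hrec[1, 1], hrec[1, 2], if (w == 1) 1 else if (w == 6) -1 else 0)
      if (hx[3] != 0) anyWedge <- TRUE
    }
  }
  if (!anyWedge) return(NA_character_)
  all4 <- c(pts, if (withH) list(hx))
  p <- do.call(rbind, all4[prio])
  v1 <- p[1, ] - p[4, ]; v2 <- p[2, ] - p[4, ]; v3 <- p[3, ] - p[4, ]
  det3 <- v1[1] * (v2[2] * v3[3] - v2[3] * v3[2]) -
          v1[2] * (v2[1] * v3[3] - v2[3] * v3[1]) +
          v1[3] * (v2[1] * v3[2] - v2[2] * v3[1])
  if (abs(det3) < 1e-9) return(NA_character_)
  if (det3 < 0) "R" else "S"
}

.doubleBondCandidates <- function(mg, nbrs) {
  which(mg$bonds$order == 2 & !mg$ringb &
        vapply(seq_len(nrow(mg$bonds)), function(i) {
          a <- mg$bonds$a[i]; b <- mg$bonds$b[i]
          na <- setdiff(nbrs[[a]], b); nb2 <- setdiff(nbrs[[b]], a)
          length(na) >= 1L && length(nb2) >= 1L &&
            length(na) + mg$hyd[a] == 2L && length(nb2) + mg$hyd[b] == 2L
        }, logical(1)))
}

.ezLabel <- function(mg, bondIdx, nbrs) {
  a <- mg$bonds$a[bondIdx]; b <- mg$bonds$b[bondIdx]
  hi <- function(center, other) {
    cand <- setdiff(nbrs[[center]], other)
    if (length(cand) == 1L) return(cand)
    cmp <- cipCompareBranches(mg, center, cand[1], cand[2])
    if (cmp == 0L) return(NA_integer_)               # not stereogenic
    if (cmp > 0L) cand[1] else cand[2]
  }
  ha <- hi(a, b); hb <- hi(b, a)
  if (is.na(ha) || is.na(hb)) return(NA_character_)
  d <- c(mg$x[b] - mg$x[a], mg$y[b] - mg$y[a])
  side <- function(at, from)
    d[1] * (mg$y[at] - mg$y[from]) - d[2] * (mg$x[at] - mg$x[from])
  sa <- side(ha, a); sb <- side(hb, b)
  if (abs(sa) < 1e-6 || abs(sb) < 1e-6) return("?")
  if (sign(sa) == sign(sb)) "Z" else "E"
}

#' Stereo signature of a compound
#'
#' CIP-style descriptors (R/S for tetrahedral centers, E/Z for stereogenic
#' double bonds, "?" when unspecified) listed over the compound's
#' stereocenters in canonical atom order. Two compounds are stereoisomers iff
#' they share a constitution (stereo-free canonical SMILES) and differ in
#' signature.
#'
#' @param mg a compound's molecular graph.
#' @return character vector of descriptors (empty for achiral compounds).
#' @export
stereoSignature <- function(mg) {
  if (!is.null(mg$.signature)) return(mg$.signature)
  nbrs <- molNeighbors(mg)
  rk <- canonicalRanks(mg)
  entries <- list()
  for (at in .tetrahedralCandidates(mg, nbrs)) {
    withH <- mg$hyd[at] == 1L
    prio <- .cipRankNeighbors(mg, at, nbrs[[at]], withH)
    if (is.null(prio)) next                          # not a stereocenter
    lab <- .parityFromGeometry(mg, at, nbrs[[at]], prio, withH)
    entries[[length(entries) + 1L]] <-
      list(key = rk[at] * 1000, lab = if (is.na(lab)) "?" else lab)
  }
  for (bi in .doubleBondCandidates(mg, nbrs)) {
    lab <- .ezLabel(mg, bi, nbrs)
    if (is.na(lab)) next                             # equal branches
    a <- mg$bonds$a[bi]; b <- mg$bonds$b[bi]
    entries[[length(entries) + 1L]] <-
      list(key = min(rk[a], rk[b]) * 1000 + max(rk[a], rk[b]), lab = lab)
  }
  if (!length(entries)) return(character(0))
  ord <- order(vapply(entries, `[[`, numeric(1), "key"))
  vapply(entries[ord], `[[`, character(1), "lab")
}
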