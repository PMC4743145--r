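## Colored subgraph monomorphism.
##
## Substructure matching uses element identity on atoms and (match order,
## ring membership) identity on bonds; a ring bond of the parent molecule may
## only map onto a ring bond of the target. igraph's LAD solver handles
## non-induced matching but not edge colors, so each bond is subdivided into
## a colored pseudo-vertex and colors are enforced through LAD's domain
## mechanism.

.matchPrep <- function(elem, bonds) {
  n <- length(elem)
  nb <- nrow(bonds)
  vcol <- c(paste0("a:", elem),
            if (nb) paste0("b:", bonds$morder, ":", bonds$ringb) else character(0))
  edges <- if (nb) {
    rbind(cbind(bonds$a, n + seq_len(nb)), cbind(bonds$b, n + seq_len(nb)))
  } else matrix(integer(0), ncol = 2)
  g <- igraph::make_graph(edges = t(edges), n = n + nb, directed = FALSE)
  list(g = g, vcol = vcol, nAtoms = n, nBonds = nb)
}

#' Matching prep for a molgraph (cached on the object)
#' @keywords internal
targetPrep <- function(mg) {
  if (!is.null(mg$.prep)) return(mg$.prep)
  b <- mg$bonds
  b$morder <- mg$morder
  b$ringb <- mg$ringb
  .matchPrep(mg$elem, b)
}

#' Attach cached matching prep to a molgraph
#' @keywords internal
withPrep <- function(mg) { mg$.prep <- targetPrep(mg); mg }

.ladDomains <- function(pat, tgt) {
  byCol <- split(seq_along(tgt$vcol), tgt$vcol)
  lapply(pat$vcol, function(cl) {
    d <- byCol[[cl]]
    if (is.null(d)) integer(0) else d
  })
}

#' Does a colored pattern embed (monomorphism) into a target molecule?
#'
#' @param patElem,patBonds pattern atoms (elements) and bonds
#'   (a, b, morder, ringb).
#' @param tgt a prep from [targetPrep()].
#' @keywords internal
embedsIn <- function(patElem, patBonds, tgt) {
  if (length(patElem) == 0L) return(TRUE)
  if (nrow(patBonds) == 0L)
    return(all(paste0("a:", patElem) %in% tgt$vcol[seq_len(tgt$nAtoms)]))
  pat <- .matchPrep(patElem, patBonds)
  dom <- .ladDomains(pat, tgt)
  if (any(vapply(dom, length, integer(1)) == 0L)) return(FALSE)
  igraph::subgraph_isomorphic(pat$g, tgt$g, method = "lad",
                              induced = FALSE, domains = dom)
}

#' All monomorphisms of a pattern into a target
#'
#' @return list of integer vectors, each mapping pattern atom index ->
#'   target atom index.
#' @keywords internal
allEmbeddings <- function(patElem, patBonds, tgt) {
  n <- length(patElem)
  if (n == 0L) return(list())
  if (nrow(patBonds) == 0L) {
    stopifnot(n == 1L)
    hits <- which(tgt$vcol[seq_len(tgt$nAtoms)] == paste0("a:", patElem))
    return(lapply(hits, identity))
  }
  pat <- .matchPrep(patElem, patBonds)
  dom <- .ladDomains(pat, tgt)
  if (any(vapply(dom, length, integer(1)) == 0L)) return(list())
  maps <- igraph::subgraph_isomorphisms(pat$g, tgt$g, method = "lad",
                                        induced = FALSE, domains = dom)
  lapply(maps, function(m) as.integer(m)[seq_len(n)])
}

## ---------------------------------------------------------------------------
## Independent brute-force matcher. Used only by the test oracles so that the
## enumeration-based MCS oracle does not share its isomorphism engine with
## the production code path.

#' Brute-force subgraph monomorphism (oracle)
#'
#' Plain backtracking over atom assignments under the same match semantics
#' (element identity; bond match order and ring flags equal).
#' @keywords internal
bruteEmbeds <- function(patElem, patBonds, tgtElem, tgtBonds) {
  np <- length(patElem)
  if (np == 0L) return(TRUE)
  ## adjacency with bond keys
  key <- function(bonds) paste0(bonds$morder, ":", bonds$ringb)
  pk <- key(patBonds); tk <- key(tgtBonds)
  tAdj <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tgtBonds))) {
    a <- tgtBonds$a[i]; b <- tgtBonds$b[i]
    assign(paste(a, b), tk[i], envir = tAdj)
    assign(paste(b, a), tk[i], envir = tAdj)
  }
  ## order pattern atoms so each (after the first) touches a previous one
  ord <- integer(0); seen <- logical(np)
  while (length(ord) < np) {
    nxt <- NA_integer_
    if (length(ord)) {
      for (i in seq_len(nrow(patBonds))) {
        a <- patBonds$a[i]; b <- patBonds$b[i]
        if (seen[a] && !seen[b]) { nxt <- b; break }
        if (seen[b] && !seen[a]) { nxt <- a; break }
      }
    }
    if (is.na(nxt)) nxt <- which(!seen)[1]
    ord <- c(ord, nxt); seen[nxt] <- TRUE
  }
  used <- logical(length(tgtElem))
  assignMap <- integer(np)
  ok <- function(pos) {
    if (pos > np) return(TRUE)
    p <- ord[pos]
    for (t in seq_along(tgtElem)) {
      if (used[t] || tgtElem[t] != patElem[p]) next
      good <- TRUE
      for (i in seq_len(nrow(patBonds))) {
        a <- patBonds$a[i]; b <- patBonds$b[i]
        other <- if (a == p) b else if (b == p) a else next
        oPos <- match(other, ord)
        if (oPos < pos) {
          got <- tAdj[[paste(t, assignMap[other])]]
          if (is.null(got) || got != pk[i]) { good <- FALSE; break }
        }
      }
      if (good) {
        used[t] <<- TRUE; assignMap[p] <<- t
        if (ok(pos + 1)) return(TRUE)
        used[t] <<- FALSE
      }
    }
    FALSE
  }
  ok(1)
}
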