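## Canonical atom ranking.
##
## Substitution-site numbering, mapping tie-breaks and stereo-signature
## ordering all require an atom ranking that is independent of the atom order
## of the input file. Ranks are defined as positions in a canonical
## depth-first traversal: initial invariants (element, degree, H count,
## charge, incident match orders) are refined Morgan-style, and remaining
## ties are resolved by exploring the tied traversal choices and keeping the
## lexicographically smallest traversal signature. Walking depth-first (as a
## SMILES writer does) makes ring atoms receive consecutive ranks around each
## ring, so e.g. the para position of a mono-numbered benzene ranks 4.

.refineInvariants <- function(mg, nbrs) {
  key <- vapply(seq_len(mg$n), function(i) {
    inc <- sort(mg$morder[mg$bonds$a == i | mg$bonds$b == i])
    paste(elementNumber(mg$elem[i]), length(nbrs[[i]]), mg$hyd[i],
          mg$charge[i], paste(inc, collapse = ","), sep = "|")
  }, character(1))
  rank <- as.integer(factor(key, levels = sort(unique(key))))
  repeat {
    key2 <- vapply(seq_len(mg$n), function(i) {
      nb <- nbrs[[i]]
      ords <- vapply(nb, function(j) {
        hit <- which((mg$bonds$a == i & mg$bonds$b == j) |
                     (mg$bonds$b == i & mg$bonds$a == j))[1]
        mg$morder[hit]
      }, numeric(1))
      nbKey <- sort(paste0(sprintf("%04d", rank[nb]), ":", ords))
      paste(sprintf("%04d", rank[i]), paste(nbKey, collapse = ";"), sep = "|")
    }, character(1))
    rank2 <- as.integer(factor(key2, levels = sort(unique(key2))))
    if (identical(rank2, rank)) break
    rank <- rank2
  }
  rank
}

#' Canonical atom ranks of a molgraph
#'
#' @param mg molgraph (or subMolgraph with a `hyd` field; when missing,
#'   hydrogen counts are treated as zero).
#' @return integer vector: rank (1..n) per input atom index.
#' @keywords internal
canonicalRanks <- function(mg) {
  if (mg$n == 0L) return(integer(0))
  if (mg$n == 1L) return(1L)
  if (is.null(mg$hyd)) mg$hyd <- integer(mg$n)
  if (is.null(mg$morder))
    mg$morder <- if (!is.null(mg$bonds$morder)) mg$bonds$morder
                 else mg$bonds$order
  nbrs <- molNeighbors(mg)
  rank <- .refineInvariants(mg, nbrs)

  bondOrd <- function(i, j) {
    hit <- which((mg$bonds$a == i & mg$bonds$b == j) |
                 (mg$bonds$b == i & mg$bonds$a == j))[1]
    mg$morder[hit]
  }
  atomTok <- function(i, ord)
    sprintf("%05.1f|%03d|%+d|%d", ord, elementNumber(mg$elem[i]),
            mg$charge[i], mg$hyd[i])

  best <- NULL   # list(sig = character vector, order = integer vector)

  ## DFS emitting a token stream; branch on tied choices, prune on prefix
  explore <- function(order, visited, stack, sig) {
    ## compare against best prefix
    if (!is.null(best)) {
      n1 <- length(sig); n2 <- length(best$sig)
      k <- min(n1, n2)
      if (k > 0) {
        cmp <- 0L
        for (t in seq_len(k)) {
          if (sig[t] < best$sig[t]) { cmp <- -1L; break }
          if (sig[t] > best$sig[t]) { cmp <- 1L; break }
        }
        if (cmp == 1L) return(invisible())
      }
    }
    if (length(order) == sum(comp)) {   # all atoms of this component placed
      if (is.null(best)) best <<- list(sig = sig, order = order)
      else {
        ## lexicographic: sig already <= best's prefix; shorter-first compare
        o <- .sigLess(sig, best$sig)
        if (o) best <<- list(sig = sig, order = order)
      }
      return(invisible())
    }
    ## take top of stack with unvisited neighbors (backtrack pops silently)
    v <- NULL
    while (length(stack)) {
      cand <- stack[[length(stack)]]
      un <- nbrs[[cand]][!visited[nbrs[[cand]]]]
      if (length(un)) { v <- cand; break }
      stack <- stack[-length(stack)]
    }
    if (is.null(v)) return(invisible())
    un <- nbrs[[v]][!visited[nbrs[[v]]]]
    keys <- rank[un]
    minK <- min(keys)
    choices <- un[keys == minK]
    for (w in choices) {
      ## ring-closure tokens: edges from w to already-visited atoms other
      ## than v, recorded by the visit position of the partner
      closures <- nbrs[[w]][visited[nbrs[[w]]] & nbrs[[w]] != v]
      cl <- sort(vapply(closures, function(u)
        sprintf("c%03d:%04.1f", match(u, order), bondOrd(w, u)), character(1)))
      tok <- c(atomTok(w, bondOrd(v, w)), cl)
      vis2 <- visited; vis2[w] <- TRUE
      explore(c(order, w), vis2, c(stack, w), c(sig, tok))
    }
    invisible()
  }

  ## handle components separately; order components by their signature
  compId <- igraph::components(igraph::make_graph(
    edges = rbind(mg$bonds$a, mg$bonds$b), n = mg$n, directed = FALSE))$membership
  pieces <- list()
  for (cid in sort(unique(compId))) {
    comp <- compId == cid
    idx <- which(comp)
    best <- NULL
    if (length(idx) == 1L) {
      pieces[[length(pieces) + 1]] <- list(sig = atomTok(idx, 0), order = idx)
      next
    }
    starts <- idx[rank[idx] == min(rank[idx])]
    for (s in starts) {
      vis <- logical(mg$n); vis[s] <- TRUE
      explore(s, vis, list(s), atomTok(s, 0))
    }
    pieces[[length(pieces) + 1]] <- best
  }
  ## components sorted by signature string (largest-first then signature)
  ord <- order(vapply(pieces, function(p) -length(p$order), numeric(1)),
               vapply(pieces, function(p) paste(p$sig, collapse = " "), character(1)))
  visitOrder <- unlist(lapply(pieces[ord], `[[`, "order"))
  ranks <- integer(mg$n)
  ranks[visitOrder] <- seq_along(visitOrder)
  ranks
}

.sigLess <- function(a, b) {
  k <- min(length(a), length(b))
  for (t in seq_len(k)) {
    if (a[t] < b[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  length(a) < length(b)
}
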