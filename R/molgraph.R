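## Internal molecular graph model.
##
## A "molgraph" is a plain list describing the heavy-atom graph of one
## molecule: explicit hydrogens are suppressed into per-atom hydrogen counts
## (their coordinates/wedges are retained for stereo perception). Kekule bond
## orders are kept for valence and CIP work; a parallel "match order" channel
## carries 1.5 for bonds OpenBabel perceives as aromatic, so that substructure
## matching is independent of the Kekule structure an input file happens to
## use.

.ELEMNUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
              S = 16, Cl = 17, Br = 35, I = 53, Se = 34, As = 33, "*" = 0)

elementNumber <- function(elem) {
  n <- .ELEMNUM[elem]
  n[is.na(n)] <- 99
  unname(n)
}

## default valence used for implicit hydrogen counting
.implicitH <- function(elem, charge, bondOrderSum) {
  base <- switch(elem,
    B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
    Cl = 1, Br = 1, I = 1, -1)
  if (base < 0) return(0L)                 # metals/others: no implicit H
  v <- base
  if (elem %in% c("N", "P", "O", "S")) v <- v + charge
  if (elem %in% c("C", "Si")) v <- v - abs(charge)
  if (elem %in% c("P", "S") && bondOrderSum > v) {
    ## hypervalent P(5), S(4/6)
    for (alt in if (elem == "P") 5 else c(4, 6))
      if (bondOrderSum <= alt + charge) { v <- alt + charge; break }
  }
  max(0L, as.integer(floor(v - bondOrderSum + 1e-9)))
}

#' Build a molgraph from a parsed SDF record
#'
#' @param sdf a `ChemmineR::SDF` object.
#' @param molblock raw molfile text for the record (through "M  END").
#' @return molgraph list, or NULL when the block has no atoms.
#' @keywords internal
molgraphFromSDF <- function(sdf, molblock) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) return(NULL)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  x <- unname(ab[, "C1"]); y <- unname(ab[, "C2"])
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else integer(n)

  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(a = integer(0), b = integer(0), order = integer(0),
               wedge = integer(0))
  } else {
    data.frame(a = as.integer(bb[, "C1"]), b = as.integer(bb[, "C2"]),
               order = as.integer(bb[, "C3"]),
               wedge = if ("C4" %in% colnames(bb)) as.integer(bb[, "C4"])
                       else integer(nrow(bb)))
  }

  oldCode <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else NULL
  .assembleMolgraph(elem, x, y, parity, bonds, molblock, oldCode)
}

#' Minimal raw molfile reader
#'
#' Fallback for connection tables ChemmineR flags as invalid (e.g. molecules
#' without bonds); reads only what the package needs.
#' @keywords internal
molgraphFromRawMolblock <- function(molblock) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  n <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nb <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(n) || is.na(nb) || n < 1L || length(lines) < 4L + n + nb)
    return(NULL)
  atomLines <- lines[5:(4 + n)]
  elem <- trimws(substr(atomLines, 32, 34))
  if (any(!nzchar(elem))) return(NULL)
  x <- as.numeric(substr(atomLines, 1, 10))
  y <- as.numeric(substr(atomLines, 11, 20))
  parity <- suppressWarnings(as.integer(substr(atomLines, 40, 42)))
  parity[is.na(parity)] <- 0L
  oldCode <- suppressWarnings(as.integer(substr(atomLines, 37, 39)))
  oldCode[is.na(oldCode)] <- 0L
  bonds <- if (nb > 0L) {
    bl <- lines[(5 + n):(4 + n + nb)]
    data.frame(a = as.integer(substr(bl, 1, 3)),
               b = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)),
               wedge = {
                 w <- suppressWarnings(as.integer(substr(bl, 10, 12)))
                 w[is.na(w)] <- 0L
                 w
               })
  } else data.frame(a = integer(0), b = integer(0), order = integer(0),
                    wedge = integer(0))
  .assembleMolgraph(elem, x, y, parity, bonds, molblock, oldCode)
}

.assembleMolgraph <- function(elem, x, y, parity, bonds, molblock, oldCode) {
  n <- length(elem)
  ## charges: prefer M  CHG lines, else old-style atom-block charge codes
  charge <- integer(n)
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  chgLines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chgLines)) {
    for (ln in chgLines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      for (i in seq_len(k)) charge[f[2 * i]] <- f[2 * i + 1]
    }
  } else if (!is.null(oldCode)) {
    map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
    hit <- oldCode != 0 & as.character(oldCode) %in% names(map)
    charge[hit] <- map[as.character(oldCode[hit])]
  }

  mg <- list(n = n, elem = elem, charge = charge, x = x, y = y,
             parity = parity, bonds = bonds, title = "")
  mg <- .suppressExplicitH(mg)
  mg <- .perceiveRings(mg)
  arom <- tryCatch(perceiveAromaticBonds(molblock, mg$bonds),
                   error = function(e) logical(nrow(mg$bonds)))
  ## only ring bonds can be aromatic for matching purposes
  mg$arom <- arom & mg$ringb
  mg$morder <- ifelse(mg$arom, 1.5, mg$bonds$order)
  mg$hyd <- .hydrogenCounts(mg)
  mg$molblock <- molblock
  mg
}

.suppressExplicitH <- function(mg) {
  isH <- mg$elem == "H"
  if (!any(isH)) { mg$hexp <- rep(list(NULL), mg$n); mg$nHexp <- integer(mg$n); return(mg) }
  keep <- which(!isH)
  idxMap <- integer(mg$n); idxMap[keep] <- seq_along(keep)
  hexp <- rep(list(NULL), length(keep))
  nHexp <- integer(length(keep))
  bonds <- mg$bonds
  dropB <- logical(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a[i]; b <- bonds$b[i]
    if (isH[a] && isH[b]) { dropB[i] <- TRUE; next }
    if (isH[a] || isH[b]) {
      heavy <- if (isH[a]) b else a
      h <- if (isH[a]) a else b
      j <- idxMap[heavy]
      nHexp[j] <- nHexp[j] + 1L
      ## keep the H position and wedge (narrow end at heavy atom) for stereo
      w <- if (bonds$a[i] == heavy) bonds$wedge[i] else 0L
      hexp[[j]] <- rbind(hexp[[j]], c(mg$x[h], mg$y[h], w))
      dropB[i] <- TRUE
    }
  }
  bonds <- bonds[!dropB, , drop = FALSE]
  bonds$a <- idxMap[bonds$a]; bonds$b <- idxMap[bonds$b]
  rownames(bonds) <- NULL
  list(n = length(keep), elem = mg$elem[keep], charge = mg$charge[keep],
       x = mg$x[keep], y = mg$y[keep], parity = mg$parity[keep],
       bonds = bonds, title = mg$title, hexp = hexp, nHexp = nHexp)
}

.perceiveRings <- function(mg) {
  nb <- nrow(mg$bonds)
  if (nb == 0L) { mg$ringb <- logical(0); mg$ringa <- logical(mg$n); return(mg) }
  g <- igraph::make_graph(edges = rbind(mg$bonds$a, mg$bonds$b),
                          n = mg$n, directed = FALSE)
  br <- igraph::bridges(g)
  ringb <- !(seq_len(nb) %in% as.integer(br))
  mg$ringb <- ringb
  mg$ringa <- logical(mg$n)
  if (any(ringb)) {
    ra <- unique(c(mg$bonds$a[ringb], mg$bonds$b[ringb]))
    mg$ringa[ra] <- TRUE
  }
  mg
}

.hydrogenCounts <- function(mg) {
  osum <- numeric(mg$n)
  if (nrow(mg$bonds)) {
    ord <- ifelse(mg$bonds$order == 4, 1.5, mg$bonds$order)
    for (i in seq_len(nrow(mg$bonds))) {
      osum[mg$bonds$a[i]] <- osum[mg$bonds$a[i]] + ord[i]
      osum[mg$bonds$b[i]] <- osum[mg$bonds$b[i]] + ord[i]
    }
  }
  ## explicit (suppressed) hydrogens already count as one bond each
  vapply(seq_len(mg$n), function(i)
    .implicitH(mg$elem[i], mg$charge[i], osum[i] + mg$nHexp[i]) + mg$nHexp[i],
    integer(1))
}

#' Neighbor list of a molgraph
#' @keywords internal
molNeighbors <- function(mg) {
  nb <- vector("list", mg$n)
  for (i in seq_len(nrow(mg$bonds))) {
    a <- mg$bonds$a[i]; b <- mg$bonds$b[i]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

#' Write a V2000 molfile from atom/bond tables
#'
#' Match-order 1.5 (aromatic) is written as molfile order 4, which OpenBabel
#' reads back as aromatic.
#' @keywords internal
writeMolblock <- function(elem, charge, x, y, bonds, title = "") {
  n <- length(elem)
  nb <- nrow(bonds)
  ord <- bonds$order
  ord[abs(ord - 1.5) < 1e-9] <- 4
  lines <- c(title, "  sarlattice 2D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              x[i], y[i], 0, elem[i]))
  for (i in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d%3d  0  0  0",
                              bonds$a[i], bonds$b[i], as.integer(ord[i]),
                              if (!is.null(bonds$wedge)) as.integer(bonds$wedge[i]) else 0L))
  chg <- which(charge != 0)
  for (i in chg)
    lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i, charge[i]))
  paste(c(lines, "M  END"), collapse = "\n")
}

#' Extract an induced piece of a molgraph as a standalone subgraph
#'
#' @param mg molgraph.
#' @param atoms atom indices to keep (order defines the new numbering).
#' @param bondIdx optional bond rows to keep; default: all bonds among `atoms`.
#' @return list with elem/charge/bonds (order, morder, ringb from parent).
#' @keywords internal
subMolgraph <- function(mg, atoms, bondIdx = NULL) {
  idxMap <- integer(mg$n); idxMap[atoms] <- seq_along(atoms)
  if (is.null(bondIdx))
    bondIdx <- which(mg$bonds$a %in% atoms & mg$bonds$b %in% atoms)
  b <- mg$bonds[bondIdx, , drop = FALSE]
  bonds <- data.frame(a = idxMap[b$a], b = idxMap[b$b], order = b$order,
                      morder = mg$morder[bondIdx], ringb = mg$ringb[bondIdx])
  rownames(bonds) <- NULL
  list(n = length(atoms), elem = mg$elem[atoms], charge = mg$charge[atoms],
       x = mg$x[atoms], y = mg$y[atoms], bonds = bonds,
       srcAtoms = atoms, srcBonds = bondIdx)
}

#' Constitution-level canonical SMILES for a subgraph of a molecule
#'
#' Optionally adds attachment-point dummy atoms ("*") bonded to the listed
#' fragment atoms.
#' @keywords internal
subgraphSmiles <- function(sub, attachTo = integer(0), attachOrder = NULL) {
  elem <- sub$elem; charge <- sub$charge
  x <- if (!is.null(sub$x)) sub$x else numeric(sub$n)
  y <- if (!is.null(sub$y)) sub$y else numeric(sub$n)
  bonds <- sub$bonds[, c("a", "b", "order")]
  if (length(attachTo)) {
    if (is.null(attachOrder)) attachOrder <- rep(1L, length(attachTo))
    for (k in seq_along(attachTo)) {
      elem <- c(elem, "*"); charge <- c(charge, 0L)
      x <- c(x, 0); y <- c(y, 0)
      bonds <- rbind(bonds, data.frame(a = attachTo[k], b = length(elem),
                                       order = attachOrder[k]))
    }
  }
  mb <- writeMolblock(elem, charge, x, y, bonds)
  canonicalSmiles(mb, stereo = FALSE)
}
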