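## Synthetic analog-series generator and brute-force oracles.
##
## Molecules are assembled as SMILES from a core template with {R1}..{Rn}
## placeholders; substituents are taken from per-site pools by deterministic
## cycling (entry k occupying a site receives the pool entry ((k-1) mod
## poolsize)+1), so a spec realizes the same constitutions on every run.
## Potencies follow an additive model: base + per-substituent effects +
## seeded Gaussian noise. 2D structures (wedge bonds, double-bond geometry)
## come from the OpenBabel CLI (--gen2d); the timestamp OpenBabel writes
## into molfile line 2 is normalized so identical (spec, seed) pairs give
## byte-identical files.

#' Construct a fixture specification
#'
#' @param coreTemplate SMILES with `{R1}`..`{Rn}` placeholders; a placeholder
#'   is replaced by `(substituent)` or removed entirely for H.
#' @param substituentPools list (one per site) of data.frames with columns
#'   `smiles` and `effect` (potency increment, log units).
#' @param occupancyPattern list of integer vectors; each entry realizes one
#'   compound occupying exactly those sites.
#' @param stereoPattern named list: occupancy entry index (as character) ->
#'   number of stereoisomer variants to emit. The entry's lowest occupied
#'   site is forced to the pool's first stereo-capable (`@`-bearing)
#'   substituent; variants enumerate sign flips of the chiral marks.
#' @param basePotency potency of the bare core (default 6.0).
#' @param noiseSd s.d. of the noise term (default 0.2 log units).
#' @param potencyFields SD tag name(s) to write (default "pKi").
#' @param targetEffects named numeric: constant offset added to the named
#'   extra potency fields (selectivity fixtures).
#' @param seed RNG seed for the noise draws.
#' @return a [FixtureSpec-class]
#' @export
fixtureSpec <- function(coreTemplate, substituentPools, occupancyPattern,
                        stereoPattern = list(), basePotency = 6.0,
                        noiseSd = 0.2, potencyFields = "pKi",
                        targetEffects = numeric(0), seed = 1L) {
  obj <- new("FixtureSpec", coreTemplate = coreTemplate,
             substituentPools = substituentPools,
             occupancyPattern = occupancyPattern,
             stereoPattern = stereoPattern, basePotency = basePotency,
             noiseSd = noiseSd, potencyFields = potencyFields,
             targetEffects = targetEffects, seed = as.integer(seed))
  validObject(obj)
  obj
}

.applyTemplate <- function(template, groups) {
  ## groups: character vector indexed by site ("" = H)
  out <- template
  for (k in seq_along(groups)) {
    rep <- if (nzchar(groups[k])) paste0("(", groups[k], ")") else ""
    out <- gsub(paste0("{R", k, "}"), rep, out, fixed = TRUE)
  }
  out
}

.flipStereo <- function(smiles, mask) {
  ## tokens: maximal runs of "@"; bit i of mask flips token i
  chars <- strsplit(smiles, "")[[1]]
  out <- character(0)
  i <- 1L; tok <- 0L
  while (i <= length(chars)) {
    if (chars[i] == "@") {
      len <- 1L
      while (i + len <= length(chars) && chars[i + len] == "@") len <- len + 1L
      tok <- tok + 1L
      flip <- bitwAnd(mask, bitwShiftL(1L, tok - 1L)) > 0L
      newLen <- if (flip) (if (len == 1L) 2L else 1L) else len
      out <- c(out, strrep("@", newLen))
      i <- i + len
    } else {
      out <- c(out, chars[i]); i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

.countStereoTokens <- function(smiles)
  length(gregexpr("@+", smiles)[[1]][gregexpr("@+", smiles)[[1]] > 0])

.validatePools <- function(spec) {
  n <- length(spec@substituentPools)
  for (k in seq_len(n)) {
    pool <- spec@substituentPools[[k]]
    for (smi in pool$smiles) {
      if (identical(smi, "H")) next
      groups <- rep("", n); groups[k] <- smi
      test <- .applyTemplate(spec@coreTemplate, groups)
      ok <- tryCatch(nzchar(trimws(obConvert("SMI", "CAN", test))),
                     error = function(e) FALSE)
      if (!ok)
        stop("invalid substituent SMILES '", smi, "' at site ", k)
    }
  }
}

#' Generate an analog-series SD file from a fixture specification
#'
#' @param spec a [FixtureSpec-class].
#' @param path output SD file path.
#' @return number of generated compounds (invisibly carries a `manifest`
#'   attribute: data.frame with id, smiles, occupied-site label, summed
#'   substituent effect and potency values).
#' @examples
#' path <- tempfile(fileext = ".sdf")
#' n <- generateSeriesSDF(defaultFixtureSpec(), path)
#' n
#' @export
generateSeriesSDF <- function(spec, path) {
  .validatePools(spec)
  nSites <- length(spec@substituentPools)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec@seed)

  drawCount <- integer(nSites)
  rows <- list()
  for (ei in seq_along(spec@occupancyPattern)) {
    sites <- sort(spec@occupancyPattern[[ei]])
    groups <- rep("", nSites)
    effect <- 0
    for (s in sites) {
      drawCount[s] <- drawCount[s] + 1L
      pool <- spec@substituentPools[[s]]
      pick <- ((drawCount[s] - 1L) %% nrow(pool)) + 1L
      groups[s] <- pool$smiles[pick]
      effect <- effect + pool$effect[pick]
    }
    nVar <- 1L
    key <- as.character(ei)
    if (!is.null(spec@stereoPattern[[key]])) {
      nVar <- as.integer(spec@stereoPattern[[key]])
      lo <- min(sites)
      pool <- spec@substituentPools[[lo]]
      cand <- grep("@", pool$smiles, value = TRUE)
      if (!length(cand))
        stop("stereo pattern at entry ", ei,
             " needs a stereo-capable substituent in the pool of site ", lo)
      prev <- match(groups[lo], pool$smiles)
      groups[lo] <- cand[1]
      effect <- effect - pool$effect[prev] +
        pool$effect[match(cand[1], pool$smiles)]
    }
    baseSmi <- .applyTemplate(spec@coreTemplate, groups)
    if (nVar > 2L^.countStereoTokens(baseSmi))
      stop("entry ", ei, ": ", nVar, " stereo variants need more chiral ",
           "marks than the substituents provide")
    for (v in seq_len(nVar)) {
      smi <- .flipStereo(baseSmi, v - 1L)
      rows[[length(rows) + 1L]] <-
        list(smiles = smi, label = combinationLabel(sites), effect = effect)
    }
  }

  ids <- sprintf("CPD-%03d", seq_along(rows))
  pots <- matrix(NA_real_, nrow = length(rows),
                 ncol = length(spec@potencyFields))
  colnames(pots) <- spec@potencyFields
  for (i in seq_along(rows)) {
    for (j in seq_along(spec@potencyFields)) {
      f <- spec@potencyFields[j]
      off <- if (f %in% names(spec@targetEffects)) spec@targetEffects[[f]] else 0
      pots[i, j] <- spec@basePotency + rows[[i]]$effect + off +
        stats::rnorm(1, 0, spec@noiseSd)
    }
  }

  smiFile <- tempfile(fileext = ".smi")
  on.exit(unlink(smiFile), add = TRUE)
  writeLines(sprintf("%s %s", vapply(rows, `[[`, character(1), "smiles"), ids),
             smiFile)
  sdfLines <- suppressWarnings(
    system2("obabel", c("-ismi", shQuote(smiFile), "-osdf", "--gen2d"),
            stdout = TRUE, stderr = FALSE))
  nOut <- sum(grepl("^\\$\\$\\$\\$", sdfLines))
  if (nOut != length(rows))
    stop("structure generation produced ", nOut, " of ", length(rows),
         " molecules; check the core template and substituent pools")

  ## normalize the OpenBabel timestamp header and append potency tags
  recs <- .splitSdfRecords(sdfLines)
  out <- character(0)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    rec[2] <- "  sarlattice fixture 2D"
    tags <- character(0)
    for (j in seq_len(ncol(pots)))
      tags <- c(tags, sprintf(">  <%s>", colnames(pots)[j]),
                sprintf("%.3f", pots[i, j]), "")
    out <- c(out, rec, tags, "$$$$")
  }
  con <- file(path, open = "wb")
  writeLines(out, con, sep = "\n")
  close(con)

  manifest <- data.frame(
    id = ids,
    smiles = vapply(rows, `[[`, character(1), "smiles"),
    label = vapply(rows, `[[`, character(1), "label"),
    effect = vapply(rows, `[[`, numeric(1), "effect"),
    stringsAsFactors = FALSE)
  manifest <- cbind(manifest, as.data.frame(pots))
  res <- length(rows)
  attr(res, "manifest") <- manifest
  invisible(res)
}

#' Default demo fixture: 25 analogs over a 5-site core
#'
#' A benzamide-piperidine core with five substitution sites, twelve occupied
#' site combinations including the bare core and a four-site combination
#' ("1345") holding six analogs, among them a three-member stereoisomer set.
#' Mirrors the shape of a mid-size lead-optimization series.
#'
#' @param seed RNG seed for the potency noise (default 42).
#' @return a [FixtureSpec-class]
#' @export
defaultFixtureSpec <- function(seed = 42L) {
  pools <- list(
    data.frame(smiles = c("C", "CC", "Cl", "O", "[C@@H](O)[C@H](C)O"),
               effect = c(0.3, 0.5, 0.8, -0.2, 0.4)),
    data.frame(smiles = c("C", "O", "F", "N"),
               effect = c(0.2, 0.4, 0.6, -0.3)),
    data.frame(smiles = c("C", "CC", "O", "Br"),
               effect = c(0.1, -0.1, 0.5, 0.7)),
    data.frame(smiles = c("C", "C(C)C", "C(=O)C"),
               effect = c(0.4, 0.2, 0.9)),
    data.frame(smiles = c("C", "O", "CO"),
               effect = c(0.3, 0.6, 0.2)))
  occ <- c(list(integer(0)),
           rep(list(1L), 3), rep(list(2L), 2), rep(list(3L), 2),
           rep(list(c(1L, 2L)), 3), rep(list(c(1L, 3L)), 2),
           list(c(2L, 3L)), rep(list(c(1L, 2L, 3L)), 2),
           list(c(1L, 4L)), list(c(4L, 5L)),
           rep(list(c(1L, 3L, 4L, 5L)), 4),
           list(c(1L, 2L, 3L, 4L, 5L)))
  fixtureSpec(
    coreTemplate = "O=C(c1cc{R1}cc{R2}c1OC)NC1CC{R3}N{R4}C{R5}CC1",
    substituentPools = pools,
    occupancyPattern = occ,
    stereoPattern = list("22" = 3L),   # last "1345" entry: 3 stereoisomers
    basePotency = 6.0, noiseSd = 0.2, potencyFields = "pKi", seed = seed)
}

#' Stereo-indexing fixture: one triple and two pairs
#'
#' Eight compounds over a 2-site core (the bare core is included so that the
#' stereo-bearing substituent, shared by every substituted member, stays out
#' of the MCS): subset "1" holds a three-member stereoisomer set and subset
#' "12" two separate stereoisomer pairs, so the R-group trees exercise both
#' the single-index and the incremental-index case.
#'
#' @param seed RNG seed (default 7).
#' @return a [FixtureSpec-class]
#' @export
stereoFixtureSpec <- function(seed = 7L) {
  pools <- list(
    data.frame(smiles = "[C@@H](O)[C@H](C)O", effect = 0.4),
    data.frame(smiles = c("C", "O"), effect = c(0.2, 0.5)))
  fixtureSpec(
    coreTemplate = "c1cc{R1}cc{R2}c1",
    substituentPools = pools,
    occupancyPattern = list(integer(0), 1L, c(1L, 2L), c(1L, 2L)),
    stereoPattern = list("2" = 3L, "3" = 2L, "4" = 2L),
    basePotency = 6.5, noiseSd = 0.2, potencyFields = "pKi", seed = seed)
}

#' Small-molecule fixture family for oracle validation
#'
#' Series of molecules with at most 12 heavy atoms (single-ring cores, short
#' acyclic substituents) so the enumeration oracle [oracleMCS()] stays
#' tractable. The seed selects core, occupancy and noise deterministically.
#'
#' @param seed integer.
#' @return a [FixtureSpec-class]
#' @export
smallFixtureSpec <- function(seed = 1L) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)
  templates <- c("c1cc{R1}cc{R2}c1",       # benzene, meta sites
                 "c1c{R2}ncc{R1}c1",       # pyridine
                 "C1CC{R1}NC{R2}C1")       # piperidine
  tpl <- templates[sample.int(length(templates), 1)]
  pools <- list(
    data.frame(smiles = c("C", "O", "N", "CC"),
               effect = c(0.2, 0.4, -0.1, 0.3)),
    data.frame(smiles = c("C", "F", "O"), effect = c(0.1, 0.5, 0.3)))
  allCombos <- list(1L, 2L, c(1L, 2L))
  nEntries <- sample(3:5, 1)
  occ <- allCombos[sample.int(3, nEntries, replace = TRUE)]
  fixtureSpec(coreTemplate = tpl, substituentPools = pools,
              occupancyPattern = occ, basePotency = 5.5, noiseSd = 0.2,
              potencyFields = "pKi", seed = seed)
}

## ---------------------------------------------------------------------------
## oracles

.bondsConnected <- function(bonds, idx) {
  if (length(idx) <= 1L) return(TRUE)
  seen <- logical(length(idx))
  seen[1] <- TRUE
  repeat {
    grew <- FALSE
    for (i in which(!seen)) {
      for (j in which(seen)) {
        bi <- idx[i]; bj <- idx[j]
        if (bonds$a[bi] %in% c(bonds$a[bj], bonds$b[bj]) ||
            bonds$b[bi] %in% c(bonds$a[bj], bonds$b[bj])) {
          seen[i] <- TRUE; grew <- TRUE; break
        }
      }
    }
    if (!grew) break
  }
  all(seen)
}

.oracleBondTable <- function(mg) {
  b <- mg$bonds[, c("a", "b"), drop = FALSE]
  b$morder <- mg$morder
  b$ringb <- mg$ringb
  b
}

#' Brute-force maximum common connected substructure size (oracle)
#'
#' Exhaustively enumerates the connected edge subgraphs of the member with
#' the fewest bonds and tests each against all other members with an
#' independent backtracking matcher (same match semantics as [computeMCS()]:
#' element identity, bond match order, ring bonds onto ring bonds).
#' Restricted to small molecules; refuses anything over 12 heavy atoms or 16
#' bonds.
#'
#' @param mols list of molecular graphs (elements of a CompoundSet).
#' @return list(atoms, bonds): the maximal common subgraph size.
#' @export
oracleMCS <- function(mols) {
  if (any(vapply(mols, function(m) m$n, integer(1)) > 12L))
    stop("oracleMCS is limited to molecules with <= 12 heavy atoms")
  nb <- vapply(mols, function(m) nrow(m$bonds), integer(1))
  refI <- which.min(nb)
  ref <- mols[[refI]]
  if (nrow(ref$bonds) > 16L) stop("oracleMCS is limited to <= 16 bonds")
  others <- mols[-refI]
  otherTabs <- lapply(others, .oracleBondTable)
  refTab <- .oracleBondTable(ref)

  bestA <- 0L; bestB <- 0L
  ## single atoms
  shared <- Reduce(intersect, lapply(mols, function(m) unique(m$elem)))
  if (length(shared)) bestA <- 1L

  nbonds <- nrow(ref$bonds)
  if (nbonds > 0L) {
    for (mask in seq_len(2^nbonds) - 1L) {
      idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nbonds) - 1L)) > 0L)
      if (!length(idx)) next
      atoms <- unique(c(ref$bonds$a[idx], ref$bonds$b[idx]))
      na <- length(atoms)
      if (na < bestA || (na == bestA && length(idx) <= bestB)) next
      if (!.bondsConnected(ref$bonds, idx)) next
      idxMap <- integer(ref$n); idxMap[atoms] <- seq_along(atoms)
      pb <- refTab[idx, , drop = FALSE]
      pb$a <- idxMap[pb$a]; pb$b <- idxMap[pb$b]
      pe <- ref$elem[atoms]
      ok <- TRUE
      for (k in seq_along(others)) {
        if (!bruteEmbeds(pe, pb, others[[k]]$elem, otherTabs[[k]])) {
          ok <- FALSE; break
        }
      }
      if (ok) { bestA <- na; bestB <- length(idx) }
    }
  }
  list(atoms = bestA, bonds = bestB)
}

#' Naive subset partition recomputation (oracle)
#'
#' @param assignments named list with `nonH` site vectors (as produced by
#'   [decomposeRGroups()]) or plain integer vectors of occupied sites.
#' @return named list: subset label -> sorted compound ids.
#' @export
oraclePartition <- function(assignments) {
  out <- list()
  for (id in names(assignments)) {
    a <- assignments[[id]]
    sites <- if (is.list(a)) a$nonH else a
    lab <- combinationLabel(sort(as.integer(sites)))
    out[[lab]] <- sort(c(out[[lab]], id))
  }
  if (!length(out)) return(list())
  out[order(names(out))]
}
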