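## Shared fixtures: build molecules and compound sets from SMILES in code.

smilesToSdfFile <- function(smiles, ids = NULL, path = tempfile(fileext = ".sdf"),
                            pki = NULL, field = "pKi") {
  if (is.null(ids)) ids <- sprintf("M%02d", seq_along(smiles))
  smi <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, ids), smi)
  lines <- suppressWarnings(
    system2("obabel", c("-ismi", smi, "-osdf", "--gen2d"),
            stdout = TRUE, stderr = FALSE))
  recs <- sarlattice:::.splitSdfRecords(lines)
  out <- character(0)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    rec[2] <- "  test fixture 2D"
    v <- if (is.null(pki)) 7.0 else pki[i]
    out <- c(out, rec, sprintf(">  <%s>", field), sprintf("%.3f", v), "",
             "$$$$")
  }
  writeLines(out, path)
  path
}

smilesToCompoundSet <- function(smiles, ids = NULL, pki = NULL) {
  path <- smilesToSdfFile(smiles, ids, pki = pki)
  suppressWarnings(suppressMessages(readCompounds(path, "pKi")))
}

makeSeries <- function(cs, id = "S1") {
  new("AnalogSeries", seriesId = id, scaffoldSmiles = NA_character_,
      scaffoldLevel = "framework", memberIds = compoundIds(cs), core = NULL)
}

## benzene core with all six atoms as substitution sites (spec-style example)
benzeneCore <- function() {
  cs <- smilesToCompoundSet("c1ccccc1")
  mg <- cs@compounds[[1]]
  sub <- sarlattice:::subMolgraph(mg, seq_len(mg$n))
  rk <- sarlattice:::canonicalRanks(sub)
  perm <- order(rk)
  idxMap <- integer(mg$n); idxMap[perm] <- seq_len(mg$n)
  bb <- sub$bonds
  bb$a <- idxMap[bb$a]; bb$b <- idxMap[bb$b]
  new("CoreStructure",
      graph = list(n = mg$n, elem = sub$elem[perm],
                   charge = sub$charge[perm], bonds = bb),
      smiles = "c1ccccc1", siteAtoms = seq_len(mg$n),
      nSites = as.integer(mg$n), lowCoverage = FALSE, timedOut = FALSE)
}

## dummy core when only partition bookkeeping is exercised
dummyCore <- function(nSites) {
  new("CoreStructure",
      graph = list(n = 1L, elem = "C", charge = 0L,
                   bonds = data.frame(a = integer(0), b = integer(0),
                                      order = numeric(0), morder = numeric(0),
                                      ringb = logical(0))),
      smiles = "C", siteAtoms = seq_len(nSites), nSites = as.integer(nSites),
      lowCoverage = FALSE, timedOut = FALSE)
}

dummySeries <- function(ids, nSites, id = "S1") {
  s <- new("AnalogSeries", seriesId = id, scaffoldSmiles = NA_character_,
           scaffoldLevel = "framework", memberIds = ids, core = NULL)
  s@core <- dummyCore(nSites)
  s
}

mkAssignment <- function(id, sites, nSites, groups = NULL) {
  g <- stats::setNames(rep("H", nSites), as.character(seq_len(nSites)))
  if (is.null(groups)) groups <- sprintf("*X%d", sites)
  g[as.character(sites)] <- groups
  list(compoundId = id, groups = g,
       bridged = stats::setNames(rep(FALSE, nSites),
                                 as.character(seq_len(nSites))),
       nonH = as.integer(sort(sites)), constitution = paste0("K", id),
       signature = character(0))
}

## permute the atom numbering inside one molfile block (chemistry unchanged)
permuteMolblockAtoms <- function(molblock, seed = 1L) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  nA <- as.integer(substr(counts, 1, 3))
  nB <- as.integer(substr(counts, 4, 6))
  atomLines <- lines[5:(4 + nA)]
  bondLines <- if (nB > 0) lines[(5 + nA):(4 + nA + nB)] else character(0)
  set.seed(seed)
  perm <- sample.int(nA)            # perm[newPos] = oldIdx
  inv <- integer(nA); inv[perm] <- seq_len(nA)
  newAtoms <- atomLines[perm]
  newBonds <- vapply(bondLines, function(bl) {
    a <- inv[as.integer(substr(bl, 1, 3))]
    b <- inv[as.integer(substr(bl, 4, 6))]
    paste0(sprintf("%3d%3d", a, b), substring(bl, 7))
  }, character(1), USE.NAMES = FALSE)
  rest <- lines[-seq_len(4 + nA + nB)]
  ## remap M  CHG atom references
  rest <- vapply(rest, function(ln) {
    if (!startsWith(ln, "M  CHG")) return(ln)
    f <- strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]]
    k <- as.integer(f[1])
    for (i in seq_len(k)) f[2 * i] <- as.character(inv[as.integer(f[2 * i])])
    paste0("M  CHG", paste(sprintf("%4s", f), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
  paste(c(lines[1:4], newAtoms, newBonds, rest), collapse = "\n")
}

permuteSdfFile <- function(path, out = tempfile(fileext = ".sdf"),
                           seed = 1L, recordOrder = NULL) {
  lines <- readLines(path)
  recs <- sarlattice:::.splitSdfRecords(lines)
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  if (!is.null(recordOrder)) recs <- recs[recordOrder]
  out2 <- character(0)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    mend <- grep("^M  END", rec)[1]
    mb <- paste(rec[seq_len(mend)], collapse = "\n")
    mb2 <- permuteMolblockAtoms(mb, seed = seed + i)
    out2 <- c(out2, strsplit(mb2, "\n", fixed = TRUE)[[1]],
              rec[-seq_len(mend)], "$$$$")
  }
  writeLines(out2, out)
  out
}
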