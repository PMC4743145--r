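test_that("reading an SD file yields one record per parsable molecule, in file order", {
  path <- smilesToSdfFile(c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1"),
                          ids = c("tol", "etb", "phe"))
  cs <- readCompounds(path, "pKi")
  expect_s4_class(cs, "CompoundSet")
  expect_length(cs, 3L)
  expect_identical(compoundIds(cs), c("tol", "etb", "phe"))
})

test_that("compounds missing every configured potency field are dropped with a warning", {
  path <- smilesToSdfFile(c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1"),
                          ids = c("a", "b", "c"))
  ## strip the pKi tag from the middle record
  lines <- readLines(path)
  recs <- sarlattice:::.splitSdfRecords(lines)
  mend <- grep("^M  END", recs[[2]])[1]
  recs[[2]] <- recs[[2]][seq_len(mend)]
  writeLines(unlist(lapply(recs, function(r) c(r, "$$$$"))), path)
  expect_warning(cs <- readCompounds(path, "pKi"), "no value in any")
  expect_length(cs, 2L)
  expect_identical(compoundIds(cs), c("a", "c"))
})

test_that("multi-fragment salt entries are reduced to the largest fragment", {
  path <- smilesToSdfFile("CCc1ccccc1.Cl", ids = "salt")
  cs <- readCompounds(path, "pKi")
  mg <- cs@compounds[[1]]
  ## brute-force: fragments have 8 and 1 heavy atoms; the larger one is kept
  expect_identical(mg$n, 8L)
  expect_false("Cl" %in% mg$elem)
})

test_that("unparsable molecule blocks are skipped with a warning, others kept", {
  path <- smilesToSdfFile(c("Cc1ccccc1", "CCO"), ids = c("ok1", "ok2"))
  lines <- readLines(path)
  recs <- sarlattice:::.splitSdfRecords(lines)
  broken <- c("broken", "  test", "", "garbage counts line")
  allRecs <- c(recs[1], list(broken), recs[2])
  writeLines(unlist(lapply(allRecs, function(r) c(r, "$$$$"))), path)
  expect_warning(cs <- readCompounds(path, "pKi"), "unparsable")
  expect_identical(compoundIds(cs), c("ok1", "ok2"))
})

test_that("write/read round-trip preserves connectivity, stereo and potency", {
  path <- smilesToSdfFile(c("C[C@H](O)c1ccccc1", "C/C=C/Cl"),
                          ids = c("st1", "st2"), pki = c(6.125, 7.5))
  cs <- readCompounds(path, "pKi")
  out <- tempfile(fileext = ".sdf")
  writeCompounds(cs, out)
  cs2 <- readCompounds(out, "pKi")
  expect_identical(compoundIds(cs2), compoundIds(cs))
  expect_equal(unname(potencies(cs2)), unname(potencies(cs)))
  for (i in seq_along(cs@ids)) {
    expect_identical(cs2@compounds[[i]]$smiles, cs@compounds[[i]]$smiles)
    expect_identical(stereoSignature(cs2@compounds[[i]]),
                     stereoSignature(cs@compounds[[i]]))
  }
  ## writers are deterministic
  out2 <- tempfile(fileext = ".sdf")
  writeCompounds(cs, out2)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(out2, "raw", file.size(out2)))
})

test_that("V3000 connection tables are read", {
  smi <- tempfile(fileext = ".smi")
  writeLines("Cc1ccc(O)cc1 v3k", smi)
  sdf <- tempfile(fileext = ".sdf")
  system2("obabel", c("-ismi", smi, "-osdf", "-x3", "--gen2d", "-O", sdf),
          stderr = FALSE)
  lines <- readLines(sdf)
  ## append a potency tag before the terminator
  term <- grep("^\\$\\$\\$\\$", lines)[1]
  lines <- c(lines[seq_len(term - 1)], ">  <pKi>", "6.000", "", "$$$$")
  writeLines(lines, sdf)
  expect_true(any(grepl("V3000", readLines(sdf))))
  cs <- readCompounds(sdf, "pKi")
  expect_length(cs, 1L)
  expect_identical(cs@compounds[[1]]$n, 8L)
})

test_that("subset report rows are ordered by subset label then compound id", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(stereoFixtureSpec(), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  rep <- tempfile(fileext = ".tsv")
  writeSubsetReport(an, rep)
  tab <- read.delim(rep, colClasses = "character")
  expect_identical(names(tab)[1:3], c("series_id", "subset", "compound_id"))
  ## layer-then-sites order, ids sorted within a subset
  expect_identical(tab$subset, sort(tab$subset))
  expect_false(is.unsorted(order(tab$subset, tab$compound_id)))
  ## stereo-pair rows carry their shared index
  idx <- tab$stereo_index[tab$subset == "1"]
  expect_identical(idx, rep("1", 3))
})

test_that("graph exports cover dot, graphml and a JSON round-trip", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(stereoFixtureSpec(), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  g <- buildCompleteGraph(an@partition, cs)
  r <- reduceGraph(g)

  dotf <- tempfile(fileext = ".dot")
  exportGraph(r, "dot", dotf)
  dot <- readLines(dotf)
  expect_identical(sum(grepl("\\[", dot)), nrow(graphNodes(r)))
  expect_identical(sum(grepl("->", dot)), nrow(graphEdges(r)))

  gml <- tempfile(fileext = ".graphml")
  exportGraph(g, "graphml", gml)
  x <- readLines(gml)
  ## empty nodes flagged empty=true
  nEmptyTrue <- sum(grepl("key=\"empty\">true<", x))
  expect_identical(nEmptyTrue, sum(graphNodes(g)$empty))

  jf <- tempfile(fileext = ".json")
  exportGraph(r, "json", jf)
  r2 <- importGraphJSON(jf)
  expect_identical(graphNodes(r2)$label, graphNodes(r)$label)
  expect_identical(graphEdges(r2), graphEdges(r))
  expect_equal(graphNodes(r2)$meanPotency, graphNodes(r)$meanPotency)

  tr <- buildRGroupTree(an, "1")
  jf2 <- tempfile(fileext = ".json")
  exportGraph(tr, "json", jf2)
  tr2 <- importGraphJSON(jf2)
  expect_equal(treeNodes(tr2), treeNodes(tr))
  expect_identical(tr2@layerOrder, tr@layerOrder)

  expect_error(exportGraph(r, "gexf", tempfile()), "graphml, dot, json")
})

test_that("an empty series yields a header-only report", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(stereoFixtureSpec(), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  an@partition@members <- list()
  an@partition@labels <- character(0)
  an@partition@combinations <- list()
  rep <- tempfile(fileext = ".tsv")
  writeSubsetReport(an, rep)
  expect_length(readLines(rep), 1L)
})
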