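test_that("a mono-substituted compound maps to site 1 of a symmetric core", {
  core <- benzeneCore()
  cs <- smilesToCompoundSet("Oc1ccccc1")
  map <- mapToCore(cs@compounds[[1]], core)
  asg <- decomposeRGroups(cs@compounds[[1]], core, map)
  expect_identical(asg$nonH, 1L)
  expect_identical(unname(asg$groups[["1"]]), "*O")
})

test_that("p-cresol occupies the minimal para pair with the SMILES tie-break", {
  core <- benzeneCore()
  cs <- smilesToCompoundSet("Cc1ccc(O)cc1")
  map <- mapToCore(cs@compounds[[1]], core)
  asg <- decomposeRGroups(cs@compounds[[1]], core, map)
  expect_identical(asg$nonH, c(1L, 4L))
  ## "*C" < "*O": methyl lands on the lower site
  expect_identical(unname(asg$groups[c("1", "4")]), c("*C", "*O"))
})

test_that("atom-order permutation does not change the mapping result", {
  core <- benzeneCore()
  path <- smilesToSdfFile("Cc1ccc(O)cc1", ids = "pc")
  cs1 <- readCompounds(path, "pKi")
  cs2 <- readCompounds(permuteSdfFile(path, seed = 11), "pKi")
  a1 <- decomposeRGroups(cs1@compounds[[1]], core,
                         mapToCore(cs1@compounds[[1]], core))
  a2 <- decomposeRGroups(cs2@compounds[[1]], core,
                         mapToCore(cs2@compounds[[1]], core))
  expect_identical(a1$groups, a2$groups)
  expect_identical(a1$nonH, a2$nonH)
})

test_that("all mono-substituted members of a symmetric core share one site", {
  core <- benzeneCore()
  cs <- smilesToCompoundSet(c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1",
                              "Nc1ccccc1", "Clc1ccccc1"))
  for (mg in cs@compounds) {
    asg <- decomposeRGroups(mg, core, mapToCore(mg, core))
    expect_identical(asg$nonH, 1L)
  }
})

test_that("a compound equal to the core decomposes to all-H groups", {
  core <- benzeneCore()
  cs <- smilesToCompoundSet("c1ccccc1")
  asg <- decomposeRGroups(cs@compounds[[1]], core,
                          mapToCore(cs@compounds[[1]], core))
  expect_identical(unname(asg$groups), rep("H", 6))
  expect_length(asg$nonH, 0L)
})

test_that("decomposition round-trips: core plus groups reassembles the constitution", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(defaultFixtureSpec(), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  for (id in compoundIds(cs)[c(1, 5, 9, 14, 20, 25)]) {
    back <- reassembleConstitution(an@core, an@assignments[[id]])
    expect_identical(back, an@assignments[[id]]$constitution,
                     label = paste("compound", id))
  }
})

test_that("site numbering is independent of molecule order in the input", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(stereoFixtureSpec(), path)
  cs1 <- suppressMessages(readCompounds(path, "pKi"))
  perm <- permuteSdfFile(path, seed = 3,
                         recordOrder = rev(seq_len(length(cs1))))
  cs2 <- suppressMessages(readCompounds(perm, "pKi"))
  an1 <- suppressWarnings(analyzeSeries(makeSeries(cs1), cs1))
  an2 <- suppressWarnings(analyzeSeries(makeSeries(cs2), cs2))
  expect_identical(an1@core@siteAtoms, an2@core@siteAtoms)
  for (id in compoundIds(cs1))
    expect_identical(an1@assignments[[id]]$groups,
                     an2@assignments[[id]]$groups)
})

test_that("combining a series with itself is idempotent; unions are covered", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(smallFixtureSpec(2), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  s <- makeSeries(cs)
  expect_identical(compoundIds(combineSeries(s, s)), compoundIds(s))

  half1 <- s; half1@memberIds <- compoundIds(cs)[1:2]; half1@seriesId <- "A"
  half2 <- s; half2@memberIds <- compoundIds(cs)[-(1:2)]; half2@seriesId <- "B"
  merged <- combineSeries(half1, half2)
  expect_identical(merged@seriesId, "A+B")
  an <- suppressWarnings(analyzeSeries(merged, cs))
  expect_setequal(unlist(an@partition@members), compoundIds(cs))
})
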