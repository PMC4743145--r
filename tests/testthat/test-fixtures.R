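test_that("the generator realizes exactly the requested site combinations", {
  spec <- fixtureSpec(
    coreTemplate = "O=C(c1cc{R1}cc{R2}c1OC)NC1CC{R3}N{R4}C{R5}CC1",
    substituentPools = defaultFixtureSpec()@substituentPools,
    occupancyPattern = list(1L, c(1L, 2L), c(1L, 3L, 4L, 5L)),
    seed = 9L)
  path <- tempfile(fileext = ".sdf")
  n <- generateSeriesSDF(spec, path)
  man <- attr(n, "manifest")
  expect_identical(as.integer(n), 3L)
  expect_identical(man$label, c("1", "12", "1345"))
})

test_that("stereo patterns emit distinct stereoisomer duplicates", {
  path <- tempfile(fileext = ".sdf")
  n <- generateSeriesSDF(stereoFixtureSpec(), path)
  expect_identical(as.integer(n), 8L)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  sig <- lapply(cs@compounds, stereoSignature)
  cst <- vapply(cs@compounds, `[[`, character(1), "constitution")
  ## the three-variant entry: one constitution, three signatures
  expect_identical(length(unique(cst[2:4])), 1L)
  expect_identical(length(unique(vapply(sig[2:4], paste, character(1),
                                        collapse = ""))), 3L)
})

test_that("identical spec and seed give byte-identical SD files", {
  p1 <- tempfile(fileext = ".sdf"); p2 <- tempfile(fileext = ".sdf")
  generateSeriesSDF(defaultFixtureSpec(), p1)
  generateSeriesSDF(defaultFixtureSpec(), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("potencies follow the additive model up to the seeded noise", {
  path <- tempfile(fileext = ".sdf")
  n <- generateSeriesSDF(defaultFixtureSpec(), path)
  man <- attr(n, "manifest")
  resid <- man$pKi - (6.0 + man$effect)
  expect_true(all(abs(resid) < 5 * 0.2))
  expect_gt(stats::sd(resid), 0)
  ## the SD tags equal the manifest potencies
  cs <- suppressMessages(readCompounds(path, "pKi"))
  expect_equal(unname(potencies(cs)[man$id, 1]), round(man$pKi, 3),
               tolerance = 1e-9)
})

test_that("invalid substituent SMILES are rejected naming the site", {
  spec <- fixtureSpec(
    coreTemplate = "c1cc{R1}cc{R2}c1",
    substituentPools = list(data.frame(smiles = "]C[", effect = 0),
                            data.frame(smiles = "C", effect = 0)),
    occupancyPattern = list(1L))
  expect_error(generateSeriesSDF(spec, tempfile()), "site 1")
})

test_that("every generated molecule contains the bare template core", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(smallFixtureSpec(6), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  bare <- gsub("\\{R[0-9]+\\}", "", smallFixtureSpec(6)@coreTemplate)
  bmg <- smilesToCompoundSet(bare)@compounds[[1]]
  pb <- bmg$bonds; pb$morder <- bmg$morder; pb$ringb <- bmg$ringb
  for (mg in cs@compounds)
    expect_true(sarlattice:::embedsIn(bmg$elem, pb,
                                      sarlattice:::targetPrep(mg)))
})

test_that("oracleMCS handles the boundary examples", {
  cs <- smilesToCompoundSet(c("Cc1ccccc1", "CCc1ccccc1"))
  expect_identical(oracleMCS(cs@compounds), list(atoms = 7L, bonds = 7L))
  cs2 <- smilesToCompoundSet(c("c1ccccc1", "c1ccccc1"))
  expect_identical(oracleMCS(cs2@compounds), list(atoms = 6L, bonds = 6L))
  cs3 <- smilesToCompoundSet(c("C", "CC"))
  expect_identical(oracleMCS(cs3@compounds), list(atoms = 1L, bonds = 0L))
  ## refuses molecules beyond its size limit
  big <- smilesToCompoundSet("CCCCCCCCCCCCC")
  expect_error(oracleMCS(list(big@compounds[[1]], big@compounds[[1]])),
               "12 heavy atoms")
})

test_that("oraclePartition recomputes subsets naively", {
  expect_identical(oraclePartition(list()), list())
  asg <- list(a = mkAssignment("a", 1L, 3), b = mkAssignment("b", c(2L, 3L), 3))
  expect_identical(oraclePartition(asg), list("1" = "a", "23" = "b"))
})
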