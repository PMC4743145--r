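test_that("MCS of identical molecules is the whole molecule", {
  cs <- smilesToCompoundSet(c("Cc1ccccc1", "Cc1ccccc1"), c("a", "b"))
  core <- computeMCS(makeSeries(cs), cs)
  expect_identical(core@graph$n, 7L)
  expect_identical(nrow(core@graph$bonds), 7L)
  expect_false(core@lowCoverage)
})

test_that("MCS of toluene/ethylbenzene/p-xylene is methylbenzene", {
  cs <- smilesToCompoundSet(c("Cc1ccccc1", "CCc1ccccc1", "Cc1ccc(C)cc1"),
                            c("a", "b", "c"))
  core <- computeMCS(makeSeries(cs), cs)
  expect_identical(core@graph$n, 7L)
  expect_identical(core@smiles, "Cc1ccccc1")
  ## enumeration oracle agrees on the size
  o <- oracleMCS(cs@compounds)
  expect_identical(c(core@graph$n, nrow(core@graph$bonds)),
                   c(o$atoms, o$bonds))
})

test_that("ring-bond and bond-order matching make benzene/cyclohexane disjoint", {
  cs <- smilesToCompoundSet(c("c1ccccc1", "C1CCCCC1"), c("a", "b"))
  expect_warning(core <- computeMCS(makeSeries(cs), cs), "low coverage")
  expect_lte(core@graph$n, 1L)      # no bond can match
  expect_true(core@lowCoverage)
})

test_that("exact search equals the enumeration oracle on seeded small series", {
  for (seed in 1:6) {
    path <- tempfile(fileext = ".sdf")
    generateSeriesSDF(smallFixtureSpec(seed), path)
    cs <- suppressMessages(readCompounds(path, "pKi"))
    core <- suppressWarnings(computeMCS(makeSeries(cs), cs))
    o <- oracleMCS(cs@compounds)
    expect_identical(c(core@graph$n, nrow(core@graph$bonds)),
                     c(o$atoms, o$bonds), label = paste("seed", seed))
  }
})

test_that("the fixture MCS contains the generating core", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(smallFixtureSpec(3), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  core <- suppressWarnings(computeMCS(makeSeries(cs), cs))
  ## the bare template core must embed into the computed MCS
  spec <- smallFixtureSpec(3)
  bare <- gsub("\\{R[0-9]+\\}", "", spec@coreTemplate)
  bcs <- smilesToCompoundSet(bare)
  bare_mg <- bcs@compounds[[1]]
  pb <- bare_mg$bonds
  pb$morder <- bare_mg$morder
  pb$ringb <- bare_mg$ringb
  prep <- sarlattice:::.matchPrep(
    core@graph$elem, core@graph$bonds[, c("a", "b", "morder", "ringb")])
  expect_true(sarlattice:::embedsIn(bare_mg$elem, pb, prep))
})

test_that("MCS is invariant to molecule order and atom numbering", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(smallFixtureSpec(5), path)
  cs1 <- suppressMessages(readCompounds(path, "pKi"))
  perm <- permuteSdfFile(path, seed = 99,
                         recordOrder = rev(seq_len(length(cs1))))
  cs2 <- suppressMessages(readCompounds(perm, "pKi"))
  c1 <- suppressWarnings(computeMCS(makeSeries(cs1), cs1))
  c2 <- suppressWarnings(computeMCS(makeSeries(cs2), cs2))
  expect_identical(c1@smiles, c2@smiles)
  expect_identical(c1@graph$elem, c2@graph$elem)
  expect_identical(c1@graph$bonds$morder, c2@graph$bonds$morder)
})

test_that("single-atom overlap falls back to a one-atom core", {
  cs <- smilesToCompoundSet(c("C", "CC"), c("a", "b"))
  core <- suppressWarnings(computeMCS(makeSeries(cs), cs))
  expect_identical(core@graph$n, 1L)
  expect_identical(nrow(core@graph$bonds), 0L)
})
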