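test_that("framework extraction follows the Bemis-Murcko convention", {
  cs <- smilesToCompoundSet(c("Cc1ccccc1", "c1ccccc1", "CCC(C)C",
                              "O=C(c1ccccc1)c1ccccc1"))
  tol <- extractScaffold(cs@compounds[[1]], "framework")
  benz <- extractScaffold(cs@compounds[[2]], "framework")
  expect_identical(tol$smiles, benz$smiles)       # side chain removed
  ## idempotence: scaffold of a scaffold is itself
  expect_identical(benz$smiles,
                   extractScaffold(cs@compounds[[2]], "framework")$smiles)
  ## acyclic molecule -> sentinel
  expect_identical(extractScaffold(cs@compounds[[3]], "framework")$smiles,
                   "<acyclic>")
  ## exocyclic carbonyl O is double-bonded to the ring linker and retained
  ket <- extractScaffold(cs@compounds[[4]], "framework")
  expect_true(grepl("O", ket$smiles))
})

test_that("generic skeletons equate heteroatom-exchanged frameworks", {
  cs <- smilesToCompoundSet(c("C1CN(CCN1)c1ccccc1",    # 1-phenylpiperazine
                              "C1CCN(CC1)c1ccccc1"))   # 1-phenylpiperidine
  f1 <- extractScaffold(cs@compounds[[1]], "framework")
  f2 <- extractScaffold(cs@compounds[[2]], "framework")
  expect_false(identical(f1$smiles, f2$smiles))
  g1 <- extractScaffold(cs@compounds[[1]], "generic_skeleton")
  g2 <- extractScaffold(cs@compounds[[2]], "generic_skeleton")
  expect_identical(g1$smiles, g2$smiles)
})

test_that("series grouping partitions scaffold-bearing compounds deterministically", {
  cs <- smilesToCompoundSet(c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1"),
                            ids = c("tol", "etb", "pyr"))
  ser <- suppressMessages(groupIntoSeries(cs, minSeriesSize = 2L))
  expect_length(ser, 1L)
  expect_identical(compoundIds(ser[[1]]), c("etb", "tol"))
  expect_identical(attr(ser, "unassigned"), "pyr")    # different scaffold

  ## 5 compounds sharing one scaffold -> 1 series of 5
  cs5 <- smilesToCompoundSet(c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
                               "Oc1ccccc1", "Nc1ccccc1"))
  ser5 <- suppressMessages(groupIntoSeries(cs5))
  expect_length(ser5, 1L)
  expect_length(compoundIds(ser5[[1]]), 5L)
  ## threshold rule: minimum above the group size -> no series
  ser6 <- suppressMessages(groupIntoSeries(cs5, minSeriesSize = 6L))
  expect_length(ser6, 0L)
  expect_length(attr(ser6, "unassigned"), 5L)
})

test_that("series membership and ids are invariant to compound order", {
  smis <- c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "Cc1ccncc1",
            "C1CCCCC1", "CC1CCCCC1")
  ids <- sprintf("C%d", 1:6)
  csA <- smilesToCompoundSet(smis, ids)
  csB <- smilesToCompoundSet(rev(smis), rev(ids))
  serA <- suppressMessages(groupIntoSeries(csA))
  serB <- suppressMessages(groupIntoSeries(csB))
  expect_identical(lapply(serA, compoundIds), lapply(serB, compoundIds))
  expect_identical(vapply(serA, seriesId, character(1)),
                   vapply(serB, seriesId, character(1)))
})
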