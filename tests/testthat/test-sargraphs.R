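test_that("partitioning groups compounds by their exact non-H site sets", {
  asg <- list(c1 = mkAssignment("c1", 1L, 2, "*C"),
              c2 = mkAssignment("c2", 1L, 2, "*CC"),
              c3 = mkAssignment("c3", c(1L, 2L), 2, c("*C", "*O")))
  part <- partitionSeries(dummySeries(c("c1", "c2", "c3"), 2), asg)
  expect_identical(part@labels, c("1", "12"))
  expect_identical(part@members, list(c("c1", "c2"), "c3"))
  ## oracle agreement
  o <- oraclePartition(asg)
  expect_identical(stats::setNames(lapply(part@members, sort), part@labels),
                   o[part@labels])
})

test_that("a compound identical to the core maps to the root subset", {
  asg <- list(bare = mkAssignment("bare", integer(0), 3))
  part <- partitionSeries(dummySeries("bare", 3), asg)
  expect_identical(part@labels, "0")
  expect_identical(lengths(part@members), 1L)
})

test_that("random assignments conserve compounds and match the oracle", {
  set.seed(123)
  ids <- sprintf("c%03d", 1:25)
  asg <- lapply(ids, function(id) {
    k <- sample(0:5, 1)
    mkAssignment(id, sort(sample.int(5, k)), 5)
  })
  names(asg) <- ids
  part <- partitionSeries(dummySeries(ids, 5), asg)
  expect_identical(sum(lengths(part@members)), 25L)
  expect_false(anyDuplicated(unlist(part@members)) > 0)
  o <- oraclePartition(asg)
  expect_identical(stats::setNames(lapply(part@members, sort), part@labels),
                   o[part@labels])
})

test_that("the complete graph over 5 sites has 32 nodes, 80 edges, binomial layers", {
  asg <- list(c1 = mkAssignment("c1", 1L, 5))
  part <- partitionSeries(dummySeries("c1", 5), asg)
  cs <- smilesToCompoundSet("Cc1ccccc1", "c1")
  g <- buildCompleteGraph(part, cs)
  nd <- graphNodes(g)
  expect_identical(nrow(nd), 32L)
  expect_identical(as.integer(table(nd$layer)), as.integer(choose(5, 0:5)))
  expect_identical(nrow(graphEdges(g)), 80L)     # sum k*C(5,k)
  expect_identical(nd$label[1], "0")
})

test_that("one-site series give the 2-node, 1-edge complete graph", {
  asg <- list(c1 = mkAssignment("c1", 1L, 1))
  part <- partitionSeries(dummySeries("c1", 1), asg)
  cs <- smilesToCompoundSet("Cc1ccccc1", "c1")
  g <- buildCompleteGraph(part, cs)
  expect_identical(nrow(graphNodes(g)), 2L)
  expect_identical(nrow(graphEdges(g)), 1L)
  ## no compound at the root: the root node is empty
  expect_true(graphNodes(g)$empty[graphNodes(g)$label == "0"])
})

test_that("reduction keeps only non-empty nodes without transitive re-wiring", {
  cs <- smilesToCompoundSet(c("Cc1ccccc1", "CCc1ccccc1"), c("c1", "c3"))
  ## occupied: "1" and "123"; intermediates "12","13" empty -> isolated nodes
  asg <- list(c1 = mkAssignment("c1", 1L, 3),
              c3 = mkAssignment("c3", 1:3, 3))
  part <- partitionSeries(dummySeries(c("c1", "c3"), 3), asg)
  g <- buildCompleteGraph(part, cs)
  r <- reduceGraph(g)
  expect_identical(sort(graphNodes(r)$label), c("1", "123"))
  expect_identical(nrow(graphEdges(r)), 0L)

  ## adjacent occupied nodes keep their edge
  asg2 <- list(c1 = mkAssignment("c1", 1L, 3),
               c3 = mkAssignment("c3", c(1L, 2L), 3))
  part2 <- partitionSeries(dummySeries(c("c1", "c3"), 3), asg2)
  r2 <- reduceGraph(buildCompleteGraph(part2, cs))
  expect_identical(nrow(graphNodes(r2)), 2L)
  expect_identical(nrow(graphEdges(r2)), 1L)

  ## reduction is idempotent
  r3 <- reduceGraph(r2)
  expect_identical(graphNodes(r3), graphNodes(r2))
  expect_identical(graphEdges(r3), graphEdges(r2))
})

test_that("node statistics are count, arithmetic mean and range in log units", {
  p <- c(a = 5.0, b = 7.0, c = 8.2, d = 6.0, e = 6.0, f = 6.0)
  expect_identical(nodeStatistics(c("a", "b"), p),
                   list(count = 2L, meanPotency = 6.0, potencyRange = 2.0))
  expect_identical(nodeStatistics("c", p),
                   list(count = 1L, meanPotency = 8.2, potencyRange = 0.0))
  expect_identical(nodeStatistics(c("d", "e", "f"), p),
                   list(count = 3L, meanPotency = 6.0, potencyRange = 0.0))
  expect_identical(nodeStatistics(character(0), p)$count, 0L)
  expect_true(is.na(nodeStatistics(character(0), p)$meanPotency))
})

test_that("conservation: node counts sum to the number of partitioned compounds", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(defaultFixtureSpec(), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  g <- buildCompleteGraph(an@partition, cs)
  expect_identical(sum(graphNodes(g)$count), 25L)
  expect_identical(sum(graphNodes(reduceGraph(g))$count), 25L)
})

test_that("selectivity views share topology and expose per-node differences", {
  spec <- stereoFixtureSpec()
  spec@potencyFields <- c("pKi_A", "pKi_B")
  spec@targetEffects <- c(pKi_B = -1.5)
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(spec, path)
  cs <- suppressMessages(readCompounds(path, c("pKi_A", "pKi_B"),
                                       c("A", "B")))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  views <- buildSelectivityViews(an, "A", "B")
  gA <- views$A; gB <- views$B
  expect_identical(graphNodes(gA)$label, graphNodes(gB)$label)
  expect_identical(graphEdges(gA), graphEdges(gB))
  expect_identical(graphNodes(gA)$count, graphNodes(gB)$count)
  expect_equal(graphNodes(gA)$potencyDiff,
               graphNodes(gA)$meanPotency - graphNodes(gB)$meanPotency)
  ## the engineered offset shows up as a positive A-over-B difference
  expect_true(all(graphNodes(gA)$potencyDiff > 0))
})

test_that("selectivity requires two configured targets", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(stereoFixtureSpec(), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  expect_error(buildSelectivityViews(an, "pKi", "other"), "2 configured")
})
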