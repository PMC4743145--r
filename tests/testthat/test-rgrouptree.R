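.treeFixture <- function() {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(stereoFixtureSpec(), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  suppressWarnings(analyzeSeries(makeSeries(cs), cs))
}

test_that("layers are ordered by ascending count of distinct R-groups", {
  an <- .treeFixture()
  ## subset "12": site with one unique group must come first
  tr <- buildRGroupTree(an, "12")
  asg <- an@assignments
  ids <- an@partition@members[[match("12", an@partition@labels)]]
  nUnique <- vapply(tr@layerOrder, function(s)
    length(unique(vapply(ids, function(id)
      asg[[id]]$groups[[as.character(s)]], character(1)))), integer(1))
  expect_false(is.unsorted(nUnique))
  ## one leaf per compound, intermediate counts sum over children
  nd <- treeNodes(tr)
  expect_identical(sum(nd$type == "leaf"), length(ids))
  for (i in which(nd$type == "group")) {
    kids <- nd[!is.na(nd$parent) & nd$parent == nd$id[i], ]
    if (nrow(kids) && all(kids$type == "group"))
      expect_identical(sum(kids$count), nd$count[i])
  }
})

test_that("single-site subsets give root plus one leaf per constitution member", {
  an <- .treeFixture()
  tr <- buildRGroupTree(an, "1")
  nd <- treeNodes(tr)
  expect_identical(length(tr@layerOrder), 1L)
  expect_identical(sum(nd$type == "leaf"), 3L)
  expect_identical(sum(is.na(nd$parent)), 1L)
})

test_that("a three-member stereoisomer set shares index 1", {
  an <- .treeFixture()
  tr <- buildRGroupTree(an, "1")
  leaves <- treeNodes(tr)[treeNodes(tr)$type == "leaf", ]
  expect_identical(leaves$stereoIndex, rep(1L, 3))
})

test_that("two stereo pairs in one tree get incremental indices 1 and 2", {
  an <- .treeFixture()
  tr <- buildRGroupTree(an, "12")
  leaves <- treeNodes(tr)[treeNodes(tr)$type == "leaf", ]
  expect_identical(sort(unique(leaves$stereoIndex)), c(1L, 2L))
  expect_identical(as.integer(table(leaves$stereoIndex)[c("1", "2")]),
                   c(2L, 2L))
  ## stereo-mates are adjacent leaves
  idx <- leaves$stereoIndex
  expect_identical(idx[order(seq_along(idx))],
                   idx[order(idx, seq_along(idx))])
})

test_that("trees without stereo-mates carry no indices", {
  path <- tempfile(fileext = ".sdf")
  generateSeriesSDF(smallFixtureSpec(4), path)
  cs <- suppressMessages(readCompounds(path, "pKi"))
  an <- suppressWarnings(analyzeSeries(makeSeries(cs), cs))
  for (lab in an@partition@labels) {
    tr <- buildRGroupTree(an, lab)
    leaves <- treeNodes(tr)[treeNodes(tr)$type == "leaf", ]
    cst <- vapply(leaves$compoundId, function(id)
      an@assignments[[id]]$constitution, character(1))
    if (!any(duplicated(cst)))
      expect_true(all(is.na(leaves$stereoIndex)), label = lab)
  }
})

test_that("every stereo index class has at least two members (validity)", {
  an <- .treeFixture()
  for (lab in an@partition@labels) {
    nd <- treeNodes(buildRGroupTree(an, lab))
    si <- nd$stereoIndex[nd$type == "leaf"]
    si <- si[!is.na(si)]
    if (length(si)) expect_true(all(table(si) >= 2L))
  }
})
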