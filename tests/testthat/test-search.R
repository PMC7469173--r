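test_that("stepwise addition produces valid trees and respects compatibility", {
  # 3 areas: the unique 3-tip tree regardless of order
  pam3 <- pamFromStrings(c(A = "110", B = "011", C = "101"))
  tr <- stepwiseAddition(pam3)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  # characters perfectly compatible with ((A,B),(C,D)): recovered for every
  # addition order
  pam4 <- pamFromStrings(c(A = "1101", B = "1100", C = "0011", D = "0010"))
  target <- topologyKey(tree4("((A,B),(C,D));"))
  orders <- list(c("A","B","C","D"), c("D","C","B","A"), c("B","D","A","C"))
  for (o in orders)
    expect_equal(topologyKey(stepwiseAddition(pam4, o)), target)
  # n areas give a binary tree with 2n-3 edges
  set.seed(21)
  pam8 <- randomBinaryPam(8, 15)
  expect_equal(nrow(stepwiseAddition(pam8)$edge), 2 * 8 - 3)
  expect_error(stepwiseAddition(pamFromStrings(c(A = "1", B = "1"))),
               "at least 3")
})

test_that("TBR neighborhood covers the 4-tip space and preserves tips", {
  tr <- tree4("((A,B),(C,D));")
  nb <- tbrNeighbors(tr)
  keys <- vapply(nb, topologyKey, "")
  allKeys <- vapply(list(tree4("((A,B),(C,D));"), tree4("((A,C),(B,D));"),
                         tree4("((A,D),(B,C));")), topologyKey, "")
  # neighborhood plus the input covers all 3 topologies, input excluded
  expect_setequal(c(keys, topologyKey(tr)), allKeys)
  expect_false(topologyKey(tr) %in% keys)
  for (t in nb) expect_setequal(t$tip.label, tr$tip.label)
})

test_that("every 5-tip topology is within 2 TBR moves", {
  labs <- LETTERS[1:5]
  tr <- randomAreaTree(labs, seed = 5)
  seen <- topologyKey(tr)
  frontier <- list(tr)
  for (step in 1:2) {
    nxt <- list()
    for (t in frontier) {
      for (nb in tbrNeighbors(t)) {
        k <- topologyKey(nb)
        if (!(k %in% seen)) {
          seen <- c(seen, k)
          nxt <- c(nxt, list(nb))
        }
      }
    }
    frontier <- nxt
  }
  expect_equal(length(seen), 15L)   # (2*5-5)!! = 15 unrooted topologies
})

test_that("SPR and NNI neighborhoods are valid and nested within TBR", {
  set.seed(22)
  pam <- randomBinaryPam(6, 10)
  labs <- areaLabels(pam)
  edge <- PAEzone:::.phyloToInternal(randomAreaTree(labs), labs)
  tbr <- vapply(PAEzone:::.tbrNeighborsEdges(edge, 6L),
                PAEzone:::.treeKeyEdges, "", nTip = 6L)
  spr <- vapply(PAEzone:::.sprNeighborsEdges(edge, 6L),
                PAEzone:::.treeKeyEdges, "", nTip = 6L)
  nni <- vapply(PAEzone:::.nniNeighborsEdges(edge, 6L),
                PAEzone:::.treeKeyEdges, "", nTip = 6L)
  expect_true(all(nni %in% spr))
  expect_true(all(spr %in% tbr))
  expect_gt(length(tbr), length(nni))
})

test_that("exhaustive search finds the exact optimum and all optima", {
  # one character 1100: optimum 1, achieved only by AB|CD-compatible topology
  pam <- pamFromStrings(c(A = "11", B = "11", C = "01", D = "01"),
                        species = c("split", "anchor"))
  ex <- exhaustiveSearch(pam)
  expect_equal(ex@length, 1L)
  expect_equal(length(ex@trees), 1L)
  expect_equal(topologyKey(ex@trees[[1]]), topologyKey(tree4("((A,B),(C,D));")))
  # constant characters: optimum 0, every topology optimal
  pamC <- PresenceAbsenceMatrix(
    matrix(1L, 5, 3, dimnames = list(LETTERS[1:5], paste0("c", 1:3))))
  exC <- exhaustiveSearch(pamC)
  expect_equal(exC@length, 0L)
  expect_equal(length(exC@trees), 15L)
  # refuses more than 9 areas
  set.seed(23)
  expect_error(exhaustiveSearch(randomBinaryPam(10, 5)), "size error")
})

test_that("heuristic search matches the exhaustive optimum on random matrices", {
  set.seed(24)
  for (i in 1:25) {
    pam <- randomBinaryPam(sample(5:8, 1), sample(10:40, 1))
    h <- suppressWarnings(heuristicSearch(
      pam, searchConfig(nReplicates = 5, seed = i, steepest = TRUE,
                        maxTrees = 100)))
    expect_equal(h@length, exhaustiveSearch(pam)@length)
    # every retained tree scores exactly the reported length
    for (tr in h@trees)
      expect_equal(fitchLength(tr, pam)$length, h@length)
    # no topological duplicates in the pool
    keys <- vapply(h@trees, topologyKey, "")
    expect_equal(anyDuplicated(keys), 0L)
    # length bounds from per-character extremes
    v <- paValues(pam)
    expect_gte(h@length, sum(apply(v, 2, minSteps)))
    expect_lte(h@length, sum(apply(v, 2, maxSteps)))
  }
})

test_that("search is reproducible and respects config validation", {
  set.seed(25)
  pam <- randomBinaryPam(7, 20)
  a <- heuristicSearch(pam, searchConfig(nReplicates = 3, seed = 9))
  b <- heuristicSearch(pam, searchConfig(nReplicates = 3, seed = 9))
  expect_equal(vapply(a@trees, topologyKey, ""), vapply(b@trees, topologyKey, ""))
  expect_error(searchConfig(maxTrees = 0), "config error")
  expect_error(searchConfig(nReplicates = 0), "config error")
})

test_that("rooting on a tip preserves length and induced topology", {
  set.seed(26)
  pam <- randomBinaryPam(6, 15)
  tr <- randomAreaTree(areaLabels(pam))
  len <- fitchLength(tr, pam)$length
  rooted <- rootOn(tr, areaLabels(pam)[3])
  expect_equal(fitchLength(rooted, pam)$length, len)
  # rooting a 4-tip tree on X puts the other 3 tips in the sibling subtree
  r4 <- rootOn(tree4("((A,B),(C,D));"), "A")
  kids <- PAEzone:::.rootedCladeSets(r4)
  expect_true(any(vapply(kids, setequal, TRUE, y = c("B", "C", "D"))))
  # prune-after-root keeps the induced rooted bipartitions
  tr5 <- ape::read.tree(text = "((ROOT,(A,B)),(C,D));")
  pruned <- rootOn(tr5, "ROOT", prune = TRUE)
  expect_setequal(pruned$tip.label, c("A", "B", "C", "D"))
  sets <- PAEzone:::.rootedCladeSets(pruned)
  expect_true(any(vapply(sets, setequal, TRUE, y = c("A", "B"))))
  expect_true(any(vapply(sets, setequal, TRUE, y = c("C", "D"))))
  expect_error(rootOn(tr5, "NOPE"), "not a tip")
})
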