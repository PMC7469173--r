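test_that("bipartitions count n-3 splits and canonicalize encodings", {
  tr <- tree4("((A,B),(C,D));")
  expect_equal(length(bipartitions(tr)@splits), 1L)
  # two drawings of one topology give identical split sets
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "(((D,E),C),(B,A));")
  expect_equal(sort(bipartitions(t1, ref = "A")@keys),
               sort(bipartitions(t2, ref = "A")@keys))
  # hand enumeration for ((A,B),(C,(D,E)))
  expect_setequal(bipartitions(t1, ref = "A")@keys,
                  c("C+D+E", "D+E"))
})

test_that("strict consensus keeps exactly the shared splits", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  # identical trees: consensus is that tree
  cons <- strictConsensus(list(t1, t1), ref = "A")
  expect_setequal(bipartitions(cons, ref = "A")@keys,
                  bipartitions(t1, ref = "A")@keys)
  # total conflict on 4 tips: star tree
  all3 <- list(tree4("((A,B),(C,D));"), tree4("((A,C),(B,D));"),
               tree4("((A,D),(B,C));"))
  star <- strictConsensus(all3, ref = "A")
  expect_equal(length(bipartitions(star, ref = "A")@splits), 0L)
  # hand-worked intersection
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  cons2 <- strictConsensus(list(t1, t2), ref = "A")
  expect_equal(bipartitions(cons2, ref = "A")@keys, "C+D+E")
  expect_error(strictConsensus(list(t1, tree4("((A,B),(C,X));"))),
               "identical tip set")
})

test_that("strict consensus agrees with an independent implementation", {
  set.seed(41)
  pam <- randomBinaryPam(7, 12)
  h <- suppressWarnings(heuristicSearch(
    pam, searchConfig(nReplicates = 5, seed = 2, steepest = TRUE,
                      maxTrees = 50)))
  mine <- strictConsensus(h, ref = areaLabels(pam)[1])
  theirs <- ape::consensus(h@trees)
  expect_setequal(bipartitions(mine, ref = areaLabels(pam)[1])@keys,
                  PAEzone:::.phyloSplits(theirs, ref = areaLabels(pam)[1])$keys)
})

test_that("majority-rule consensus applies the cutoff and reports frequencies", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,B),(D,(C,E)));")
  trees <- list(t1, t1, t2)
  maj <- majorityRuleConsensus(trees, cutoff = 50, ref = "A")
  freq <- attr(maj, "splitFrequencies")
  # split D+E appears in 2 of 3 trees -> 66.7 > 50, retained
  expect_true("D+E" %in% names(freq))
  expect_equal(unname(freq[["D+E"]]), 200 / 3)
  expect_equal(unname(freq[["C+D+E"]]), 100)
  # unanimous trees: equals strict consensus
  maj2 <- majorityRuleConsensus(list(t1, t1), ref = "A")
  expect_setequal(bipartitions(maj2, ref = "A")@keys,
                  bipartitions(t1, ref = "A")@keys)
  expect_error(majorityRuleConsensus(trees, cutoff = 40), "config error")
  # retained majority splits are pairwise compatible (tree construction
  # succeeds and reproduces every retained split)
  expect_setequal(bipartitions(maj, ref = "A")@keys, names(freq))
})

test_that("bootstrap gives high support to well-backed clades", {
  sim <- simulateMatrix(simulationConfig(nAreas = 8, flipProbability = 0))
  bs <- bootstrapSupport(sim@pam, nReplicates = 100,
                         config = searchConfig(nReplicates = 3, seed = 1),
                         seed = 2)
  expect_true(all(bs@splitFrequencies >= 0 & bs@splitFrequencies <= 100))
  # supports annotated on the consensus are integers in [0, 100]
  sup <- suppressWarnings(as.numeric(bs@consensus$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup == round(sup) & sup >= 0 & sup <= 100))
  # every true clade of the noiseless fixture is strongly supported
  trueKeys <- PAEzone:::.phyloSplits(sim@trueTreeFull, ref = "ROOT")$keys
  expect_true(all(trueKeys %in% names(bs@splitFrequencies)))
  expect_true(all(bs@splitFrequencies[trueKeys] >= 95))
  # replicate matrices preserve the character count
  expect_true(all(bs@replicateLengths >= 0))
})

test_that("uninformative matrices give a star consensus with zero support", {
  v <- matrix(1L, 8, 12,
              dimnames = list(sprintf("t%02d", 1:8), sprintf("w%02d", 1:12)))
  pam <- addHypotheticalRoot(PresenceAbsenceMatrix(v))
  bs <- suppressWarnings(
    bootstrapSupport(pam, nReplicates = 20,
                     config = searchConfig(nReplicates = 5, seed = 3,
                                           maxTrees = 200),
                     seed = 4))
  expect_equal(length(bipartitions(bs@consensus, ref = "ROOT")@splits), 0L)
})

test_that("bootstrap frequencies are stable across seeds on the fixture", {
  sim <- simulateMatrix(simulationConfig())   # default: 8 areas, flip 0.05
  cfg <- searchConfig(nReplicates = 1, seed = 1)
  b1 <- bootstrapSupport(sim@pam, nReplicates = 1000, config = cfg, seed = 11)
  b2 <- bootstrapSupport(sim@pam, nReplicates = 1000, config = cfg, seed = 12)
  keys <- union(names(b1@splitFrequencies), names(b2@splitFrequencies))
  f1 <- ifelse(is.na(b1@splitFrequencies[keys]), 0, b1@splitFrequencies[keys])
  f2 <- ifelse(is.na(b2@splitFrequencies[keys]), 0, b2@splitFrequencies[keys])
  expect_lt(max(abs(f1 - f2)), 2)
})
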