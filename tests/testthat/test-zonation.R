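rootedTree <- function(newick, supports = NULL) {
  tr <- ape::read.tree(text = newick)
  if (!is.null(supports)) tr$node.label <- supports
  attr(tr, "paeRooted") <- TRUE
  tr
}

test_that("supporting species are read off the matrix, strictly and leniently", {
  sim <- simulateMatrix(simulationConfig(nAreas = 6, flipProbability = 0,
                                         nSingleton = 0))
  tr <- sim@trueTree
  attr(tr, "paeRooted") <- TRUE
  for (key in names(sim@plantedSupporters)) {
    clade <- strsplit(key, "+", fixed = TRUE)[[1]]
    sup <- supportingSpecies(tr, sim@pam, clade)
    expect_setequal(sup$strict, sim@plantedSupporters[[key]])
    expect_true(all(sup$strict %in% sup$lenient))
  }
  # widespread species support no clade strictly
  anyClade <- strsplit(names(sim@plantedSupporters)[1], "+", fixed = TRUE)[[1]]
  sup <- supportingSpecies(tr, sim@pam, anyClade)
  expect_false(any(grepl("widespread", sup$strict)))
  expect_error(supportingSpecies(tr, sim@pam, c("AR01", "nonsense")),
               "not a clade")
})

test_that("leniency admits near-endemics", {
  pam <- pamFromStrings(c(A = "111", B = "111", C = "101", D = "001"),
                        species = c("near", "anchor", "ubiquitous"))
  tr <- rootedTree("((A,B),(C,D));")
  sup <- supportingSpecies(tr, pam, c("A", "B"), leniency = 1)
  expect_false("near" %in% sup$strict)     # present in C too
  expect_true("near" %in% sup$lenient)
})

test_that("AOE detection finds planted clades, monotone in the threshold", {
  sim <- simulateMatrix(simulationConfig(nAreas = 8, flipProbability = 0,
                                         endemicsPerClade = 5))
  tr <- sim@trueTree
  attr(tr, "paeRooted") <- TRUE
  aoes <- detectAOEs(tr, sim@pam, minSupporters = 2)
  keys <- vapply(aoes, function(a) paste(a$areas, collapse = "+"), "")
  expect_setequal(keys, names(sim@plantedSupporters))
  for (a in aoes)
    expect_setequal(a$species,
                    sim@plantedSupporters[[paste(a$areas, collapse = "+")]])
  # monotone non-increasing in minSupporters
  a1 <- detectAOEs(tr, sim@pam, minSupporters = 1)
  a6 <- detectAOEs(tr, sim@pam, minSupporters = 6)
  expect_gte(length(a1), length(aoes))
  expect_lte(length(a6), length(aoes))
  # widespread-only matrix: no AOEs
  v <- matrix(1L, 6, 5, dimnames = list(sprintf("t%d", 1:6), sprintf("w%d", 1:5)))
  pamW <- PresenceAbsenceMatrix(v)
  trW <- rootedTree("((t1,t2),((t3,t4),(t5,t6)));")
  expect_equal(length(detectAOEs(trW, pamW)), 0L)
})

test_that("zonation follows the nesting rule on hand-traced trees", {
  # balanced 8-tip tree, all supports 100 -> 2 zones of 4, 2 subzones each
  bal <- rootedTree("(((A,B),(C,D)),((E,F),(G,H)));", rep("100", 7))
  zs <- extractZonation(bal)
  expect_equal(length(zs@zones), 2L)
  expect_setequal(zs@zones[[1]]$areas, c("A", "B", "C", "D"))
  expect_setequal(zs@zones[[2]]$areas, c("E", "F", "G", "H"))
  expect_equal(lengths(lapply(zs@zones, `[[`, "subzones")),
               setNames(c(2L, 2L), NULL))
  # star tree: every tip a singleton zone
  star <- rootedTree("(A,B,C,D,E);")
  zsS <- extractZonation(star)
  expect_equal(length(zsS@zones), 5L)
  expect_true(all(vapply(zsS@zones, `[[`, TRUE, "singleton")))
  expect_setequal(zsS@unplaced, c("A", "B", "C", "D", "E"))
  # caterpillar: maximal supported clade absorbs the stray tip
  cat5 <- rootedTree("((((A,B),C),D),E);", rep("100", 4))
  zsC <- extractZonation(cat5)
  expect_equal(length(zsC@zones), 1L)
  expect_setequal(zsC@zones[[1]]$areas, c("A", "B", "C", "D", "E"))
  expect_equal(zsC@zones[[1]]$subzones[["A1"]], c("A", "B"))
  # unrooted input is refused
  unrooted <- ape::read.tree(text = "(A,B,(C,(D,E)));")
  expect_error(extractZonation(unrooted), "rooted")
})

test_that("zones always partition the areas and subzones stay inside", {
  set.seed(51)
  for (i in 1:10) {
    sim <- simulateMatrix(simulationConfig(nAreas = sample(5:9, 1),
                                           flipProbability = 0.1,
                                           seed = 1000 + i))
    res <- heuristicSearch(sim@pam, searchConfig(nReplicates = 2, seed = i))
    cons <- strictConsensus(res, ref = "ROOT")
    zs <- extractZonation(rootOn(cons, "ROOT", prune = TRUE), sim@pam)
    areas <- setdiff(areaLabels(sim@pam), "ROOT")
    expect_setequal(unlist(lapply(zs@zones, `[[`, "areas")), areas)
    expect_equal(anyDuplicated(unlist(lapply(zs@zones, `[[`, "areas"))), 0L)
    for (z in zs@zones)
      for (sz in z$subzones)
        expect_true(all(sz %in% z$areas))
    expect_setequal(zs@table$area, areas)
  }
})

test_that("noiseless simulations recover the planted zone partition", {
  for (seedv in c(1, 7, 20200812)) {
    sim <- simulateMatrix(simulationConfig(nAreas = 8, flipProbability = 0,
                                           seed = seedv))
    res <- heuristicSearch(sim@pam, searchConfig(nReplicates = 3, seed = 1))
    cons <- strictConsensus(res, ref = "ROOT")
    zs <- extractZonation(rootOn(cons, "ROOT", prune = TRUE), sim@pam)
    expect_identical(PAEzone:::.zonePartitionKey(zs),
                     PAEzone:::.zonePartitionKey(sim@trueZones))
  }
})

test_that("widespread species respect the ceiling occupancy threshold", {
  set.seed(52)
  sim <- simulateMatrix(simulationConfig(nAreas = 8, flipProbability = 0))
  wide <- widespreadSpecies(sim@pam, minFraction = 0.9)
  expect_setequal(names(wide), sprintf("widespread%02d", 1:10))
  # fraction 1.0 keeps only ubiquitous species
  wide1 <- widespreadSpecies(sim@pam, minFraction = 1)
  expect_true(all(wide1 == 8L))
  # 22 areas at fraction 0.9 -> threshold ceiling(19.8) = 20
  v <- matrix(0L, 22, 2, dimnames = list(sprintf("e%02d", 1:22), c("w20", "w19")))
  v[1:20, "w20"] <- 1L
  v[1:19, "w19"] <- 1L
  pam22 <- PresenceAbsenceMatrix(cbind(v, anchor = 1L))
  w <- widespreadSpecies(pam22, minFraction = 0.9)
  expect_true("w20" %in% names(w))
  expect_false("w19" %in% names(w))
})
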