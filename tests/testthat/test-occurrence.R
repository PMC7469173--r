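test_that("occurrence records load with per-row validation", {
  path <- occurrenceCSV(c(
    "Papilio bianor,Papilionidae,IA1,lit",
    "Pieris rapae,Pieridae,IA2,lit",
    "Abisara echerius,Riodinidae,IA1,lit"))
  expect_warning(rec <- loadOccurrences(path), "failed validation")
  expect_equal(nrow(rec), 3L)
  prob <- attr(rec, "problems")
  expect_equal(prob$line, 4L)          # file line of the Riodinidae row
  expect_equal(prob$field, "family")

  # duplicate (species, area) rows both load; dedup is buildMatrix's job
  path2 <- occurrenceCSV(c(
    "Papilio bianor,Papilionidae,IA1,lit",
    "Papilio bianor,Papilionidae,IA1,specimen"))
  rec2 <- loadOccurrences(path2)
  expect_equal(nrow(rec2), 2L)

  # schema and empty-input errors
  bad <- tempfile(fileext = ".csv")
  writeLines(c("taxon,family,area", "x,Pieridae,IA1"), bad)
  expect_error(loadOccurrences(bad), "schema error")
  empty <- occurrenceCSV(character(0))
  expect_error(loadOccurrences(empty), "empty-input")
})

test_that("buildMatrix assigns 1 iff a record matches and is idempotent", {
  rec <- data.frame(species = c("sp1", "sp1", "sp2"),
                    family = "Pieridae",
                    area = c("A", "B", "A"))
  pam <- buildMatrix(rec, c("A", "B"))
  expect_equal(paValues(pam),
               matrix(c(1L, 1L, 1L, 0L), 2, 2,
                      dimnames = list(c("A", "B"), c("sp1", "sp2"))))
  # duplicated record leaves the matrix unchanged
  pam2 <- buildMatrix(rbind(rec, rec[1, ]), c("A", "B"))
  expect_identical(paValues(pam), paValues(pam2))
  # unknown area is an error naming the offender
  expect_error(buildMatrix(transform(rec, area = c("A", "ZZ", "A")),
                           c("A", "B")),
               "unknown-area.*ZZ")
  # whitespace-normalized names merge
  rec3 <- data.frame(species = c("sp1", " sp1  "), family = "Pieridae",
                     area = c("A", "B"))
  expect_equal(speciesLabels(buildMatrix(rec3, c("A", "B"))), "sp1")
})

test_that("hypothetical root is all-zero, flagged, and collision-safe", {
  pam <- pamFromStrings(c(A = "110", B = "011", C = "101"))
  rooted <- addHypotheticalRoot(pam, "ROOT")
  expect_equal(nrow(paValues(rooted)), 4L)
  expect_equal(sum(paValues(rooted)["ROOT", ]), 0L)
  expect_equal(rootArea(rooted), "ROOT")
  expect_error(addHypotheticalRoot(rooted, "ROOT"), "collision")
  # root area contributes nothing to richness
  rs <- richnessSummary(rooted)
  expect_false("ROOT" %in% names(rs@perAreaRichness))
})

test_that("richness summary matches brute-force counts, median and groups", {
  pam <- pamFromStrings(c(a = "110000000", b = "111110000", c = "111111111"))
  rs <- richnessSummary(pam)
  expect_equal(unname(rs@perAreaRichness), c(2L, 5L, 9L))
  expect_equal(rs@medianRichness, 5)
  expect_equal(rs@minAreas, "a"); expect_equal(rs@minRichness, 2L)
  expect_equal(rs@maxAreas, "c"); expect_equal(rs@maxRichness, 9L)

  # all-ones matrix: equal richness, family fractions = family share
  v <- matrix(1L, 4, 6, dimnames = list(letters[1:4], paste0("s", 1:6)))
  fam <- setNames(rep(c("Pieridae", "Lycaenidae"), c(2, 4)), paste0("s", 1:6))
  rs2 <- richnessSummary(PresenceAbsenceMatrix(v, familyOf = fam))
  expect_true(all(rs2@perAreaRichness == 6L))
  expect_equal(unname(rs2@familyFractions[, "Pieridae"]), rep(2 / 6, 4))
  expect_equal(unname(rs2@perFamilyTotals), c(4L, 2L))
  expect_equal(rowSums(rs2@familyFractions), setNames(rep(1, 4), letters[1:4]))

  # even number of areas: median = mean of the two central values
  pam4 <- pamFromStrings(c(a = "1000", b = "1100", c = "1110", d = "1111"))
  expect_equal(richnessSummary(pam4)@medianRichness, 2.5)

  # group summaries
  g <- c(a = "east", b = "east", c = "west", d = "west")
  gs <- richnessSummary(pam4, groupings = g)@groupSummaries
  expect_equal(gs$median[gs$group == "east"], 1.5)
  expect_equal(gs$max[gs$group == "west"], 4L)

  # row sums equal independent per-area record counts
  set.seed(1)
  pam5 <- randomBinaryPam(6, 30)
  expect_equal(unname(richnessSummary(pam5)@perAreaRichness),
               unname(rowSums(paValues(pam5))))
})

test_that("the shipped ecoregion configuration loads as a grouping", {
  path <- system.file("extdata", "yunnan_ecoregions_synthetic.tsv",
                      package = "PAEzone")
  df <- readAreaGroups(path)
  expect_equal(nrow(df), 22L)
  expect_equal(sum(df$climate_zone == "III"), 11L)
  side <- readAreaGroups(path, column = "side")
  expect_setequal(unique(side), c("east", "west"))
})
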