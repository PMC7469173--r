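#' Run the full PAE pipeline
#'
#' Mirrors the analysis order of a PAE study: presence-absence matrix (with
#' hypothetical root) -> heuristic parsimony search -> ensemble indices and
#' random-tree length distribution -> bootstrap -> support-annotated
#' consensus -> rooting -> zone/subzone extraction and widespread-species
#' listing.  With an output directory, all artifacts are written (Newick
#' trees, metrics JSON, split table, zonation JSON/TSV and a run log); reruns
#' with an identical configuration reproduce identical outputs.
#'
#' @param pam a [PresenceAbsenceMatrix-class]; a hypothetical root area is
#'   appended automatically when none is designated.
#' @param seed master integer seed; the search, bootstrap and random-tree
#'   seeds derive from it.
#' @param search a [searchConfig()]; its seed is overridden by `seed`.
#' @param bootstrapReplicates bootstrap replicate count.
#' @param nRandomTrees sample size for the random-tree length distribution.
#' @param supportFloor,minZoneSize,minSupporters zonation settings
#'   (see [extractZonation()]).
#' @param widespreadFraction occupancy fraction for [widespreadSpecies()].
#' @param outDir optional output directory (created if missing).
#' @return list with components `search`, `indices`, `randomTrees`,
#'   `bootstrap`, `consensus`, `rootedTree`, `zonation`, `widespread`,
#'   `summary` (a JSON-ready metrics list).
#' @export
runPAE <- function(pam, seed = 1L, search = searchConfig(),
                   bootstrapReplicates = 100L, nRandomTrees = 1000L,
                   supportFloor = 70, minZoneSize = 2L, minSupporters = 2L,
                   widespreadFraction = 0.9, outDir = NULL) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  if (is.na(rootArea(pam))) pam <- addHypotheticalRoot(pam, "ROOT")
  root <- rootArea(pam)
  search$seed <- as.integer(seed)
  bs <- bootstrapSupport(pam, nReplicates = bootstrapReplicates,
                         config = search, seed = as.integer(seed) + 1L)
  res <- bs@fullSearch
  idx <- ensembleIndices(res, pam)
  rtd <- randomTreeLengths(pam, n = nRandomTrees, seed = as.integer(seed) + 2L)
  cons <- bs@consensus
  rooted <- rootOn(cons, root, prune = TRUE)
  zs <- extractZonation(rooted, pam, supportFloor = supportFloor,
                        minZoneSize = minZoneSize,
                        minSupporters = minSupporters)
  wide <- widespreadSpecies(pam, minFraction = widespreadFraction)
  summary <- list(
    length = res@length,
    CI = idx@ci, RI = idx@ri, RC = idx@rc, HI = idx@hi,
    sums = as.list(idx@sums),
    n_mpts = length(res@trees),
    skewness = rtd@g1,
    n_zones = length(zs@zones),
    n_subzones = sum(vapply(zs@zones, function(z) length(z$subzones), 1L)),
    n_aoes = length(zs@aoes),
    n_widespread = length(wide),
    seed = as.integer(seed))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)
    ape::write.tree(do.call(c, res@trees), file = p("mpts.nwk"))
    ape::write.tree(cons, file = p("consensus.nwk"))
    ape::write.tree(rooted, file = p("rooted_consensus.nwk"))
    jsonlite::write_json(summary, p("metrics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeSplitTable(bs, p("split_frequencies.tsv"))
    writeZonation(zs, jsonPath = p("zonation.json"), tsvPath = p("zonation.tsv"))
    writeLines(c(paste("PAEzone", as.character(utils::packageVersion("PAEzone"))),
                 paste("seed:", seed),
                 paste("areas:", length(areaLabels(pam)) - 1L, "+ root"),
                 paste("species:", length(speciesLabels(pam))),
                 paste("swap:", search$swap),
                 paste("replicates:", search$nReplicates),
                 paste("bootstrap replicates:", bootstrapReplicates),
                 paste("best length:", res@length),
                 paste("MPTs:", length(res@trees))),
               p("log.txt"))
  }
  list(search = res, indices = idx, randomTrees = rtd, bootstrap = bs,
       consensus = cons, rootedTree = rooted, zonation = zs,
       widespread = wide, summary = summary)
}
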