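#' Binary areas-by-species presence-absence matrix
#'
#' The central data container of a PAE analysis.  Areas play the role of taxa
#' (rows) and species the role of characters (columns); every cell is 0, 1, or
#' `NA` for an ambiguous ("?") observation.  One area may be designated as the
#' hypothetical root: an artificial area with no species, used to root the
#' area cladogram.
#'
#' @slot values integer matrix of 0/1/`NA` with unique area row names and
#'   species column names.
#' @slot rootArea character of length 0 or 1; the designated hypothetical
#'   root area (its row must be all zero).
#' @slot familyOf named character mapping species to family (may be empty).
#' @export
setClass("PresenceAbsenceMatrix",
         representation(values = "matrix",
                        rootArea = "character",
                        familyOf = "character"))

setValidity("PresenceAbsenceMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.matrix(v) || !(is.numeric(v) || is.integer(v)))
    return("values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have area row names and species column names")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated area labels")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated species labels")
  if (any(!nzchar(rownames(v))) || any(!nzchar(colnames(v))))
    msg <- c(msg, "empty labels")
  bad <- !(v %in% c(0L, 1L)) & !is.na(v)
  if (any(bad)) msg <- c(msg, "cells must be 0, 1 or NA")
  if (length(object@rootArea) > 1L)
    msg <- c(msg, "at most one root area")
  if (length(object@rootArea) == 1L) {
    if (!object@rootArea %in% rownames(v))
      msg <- c(msg, "root area not among area labels")
    else if (any(v[object@rootArea, ] != 0, na.rm = TRUE) ||
             anyNA(v[object@rootArea, ]))
      msg <- c(msg, "root area row must be all zero")
  }
  occ <- rowSums(v == 1L, na.rm = TRUE)
  empty <- names(occ)[occ == 0L]
  empty <- setdiff(empty, object@rootArea)
  if (length(empty))
    msg <- c(msg, paste0("area(s) with no species (only the hypothetical root may be empty): ",
                         paste(empty, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceAbsenceMatrix
#'
#' @param values 0/1/`NA` matrix, areas as rows and species as columns.
#' @param rootArea optional label of the hypothetical root area.
#' @param familyOf optional named character mapping species to family.
#' @return A [PresenceAbsenceMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 1, 0, 1, 0, 1), 2, 3,
#'             dimnames = list(c("A", "B"), c("sp1", "sp2", "sp3")))
#' PresenceAbsenceMatrix(m)
#' @export
PresenceAbsenceMatrix <- function(values, rootArea = character(0),
                                  familyOf = character(0)) {
  storage.mode(values) <- "integer"
  if (length(rootArea) == 1L && is.na(rootArea)) rootArea <- character(0)
  new("PresenceAbsenceMatrix", values = values,
      rootArea = as.character(rootArea), familyOf = familyOf)
}

#' Result of a parsimony search
#'
#' @slot trees list of `phylo` trees, deduplicated by topology, all scoring
#'   exactly `length` steps.
#' @slot length integer; total Fitch length of the retained trees.
#' @slot perCharacterSteps named integer; steps per species on the first tree.
#' @slot searchLog list of search bookkeeping (replicates, seed, best length
#'   per replicate, trees scored, truncation flag).
#' @export
setClass("ParsimonyResult",
         representation(trees = "list", length = "integer",
                        perCharacterSteps = "integer", searchLog = "list"))

#' Ensemble fit indices of a tree/matrix pair
#'
#' Consistency index CI = sum(m)/sum(s), retention index
#' RI = (sum(g)-sum(s))/(sum(g)-sum(m)), rescaled consistency RC = CI*RI and
#' homoplasy index HI = 1-CI, where m, s, g are the per-character minimum,
#' observed and maximum step counts.
#'
#' @slot ci,ri,rc,hi numeric indices.
#' @slot sums named numeric: `m`, `s`, `g` sums over retained characters.
#' @slot nCharUsed integer number of characters entering the sums.
#' @slot perTree data.frame of per-tree observed sums when a result holds
#'   several equally parsimonious trees.
#' @export
setClass("EnsembleIndices",
         representation(ci = "numeric", ri = "numeric", rc = "numeric",
                        hi = "numeric", sums = "numeric",
                        nCharUsed = "integer", perTree = "data.frame"))

#' Length distribution over random topologies
#'
#' @slot lengths integer Fitch lengths of the sampled topologies.
#' @slot nTrees integer sample size.
#' @slot mean,sd,g1 numeric summary statistics; `g1` is the adjusted
#'   Fisher-Pearson sample skewness.
#' @slot seed integer seed used for sampling.
#' @export
setClass("RandomTreeDistribution",
         representation(lengths = "integer", nTrees = "integer",
                        mean = "numeric", sd = "numeric", g1 = "numeric",
                        seed = "integer"))

#' Set of tip bipartitions (splits) of a tree
#'
#' Splits are canonicalized so that the side excluding the reference tip
#' (the designated root area when available) is stored; trivial splits are
#' excluded.
#'
#' @slot splits list of character vectors (tip labels of the stored side).
#' @slot keys character split keys (sorted labels collapsed with "+").
#' @slot ref character; the reference (excluded) tip label.
#' @slot nTrees integer; number of source trees.
#' @export
setClass("BipartitionSet",
         representation(splits = "list", keys = "character",
                        ref = "character", nTrees = "integer"))

#' Bootstrap support summary
#'
#' @slot nReplicates integer number of bootstrap replicates.
#' @slot splitFrequencies named numeric; percentage (0-100) per split key.
#' @slot splitSides list of tip-label vectors matching `splitFrequencies`.
#' @slot consensus `phylo`; the support-annotated consensus tree.
#' @slot seed integer.
#' @slot replicateLengths numeric best length found in each replicate.
#' @slot fullSearch the full-data [ParsimonyResult-class].
#' @export
setClass("BootstrapSummary",
         representation(nReplicates = "integer", splitFrequencies = "numeric",
                        splitSides = "list", consensus = "ANY",
                        seed = "integer", replicateLengths = "numeric",
                        fullSearch = "ANY"))

#' Zone/subzone scheme extracted from a rooted area cladogram
#'
#' @slot zones list; each element has `label`, `areas` (clade members plus
#'   directly attached areas), `cladeAreas`, `subzones` (named list of area
#'   vectors) and `singleton` flag.
#' @slot aoes list of areas of endemism, each with `areas` and the strict
#'   supporting `species`.
#' @slot unplaced character; areas left as singleton zones.
#' @slot table data.frame with columns `area`, `zone`, `subzone`.
#' @export
setClass("ZonationScheme",
         representation(zones = "list", aoes = "list",
                        unplaced = "character", table = "data.frame"))

#' Richness summary of a presence-absence matrix
#'
#' @slot perAreaRichness named integer species counts per area (root excluded).
#' @slot familyFractions matrix area x family of per-area family fractions
#'   (zero rows when richness is 0), or a 0x0 matrix when no family map exists.
#' @slot totalSpecies integer.
#' @slot perFamilyTotals named integer.
#' @slot medianRichness numeric (mean of the two central values for an even
#'   number of areas).
#' @slot minAreas,maxAreas character; areas attaining the extreme counts.
#' @slot minRichness,maxRichness integer.
#' @slot groupSummaries data.frame with `group`, `nAreas`, `median`, `min`,
#'   `max` for a supplied area grouping.
#' @export
setClass("RichnessSummary",
         representation(perAreaRichness = "integer", familyFractions = "matrix",
                        totalSpecies = "integer", perFamilyTotals = "integer",
                        medianRichness = "numeric",
                        minAreas = "character", minRichness = "integer",
                        maxAreas = "character", maxRichness = "integer",
                        groupSummaries = "data.frame"))

#' Ground truth of a simulated PAE data set
#'
#' @slot pam the simulated [PresenceAbsenceMatrix-class] (root area included).
#' @slot trueTree rooted `phylo` over the areas (root area not a tip).
#' @slot trueTreeFull unrooted `phylo` including the root area as a tip.
#' @slot trueZones the planted [ZonationScheme-class].
#' @slot plantedSupporters named list clade key -> planted endemic species.
#' @slot config the generating configuration.
#' @export
setClass("SimulationTruth",
         representation(pam = "PresenceAbsenceMatrix", trueTree = "ANY",
                        trueTreeFull = "ANY", trueZones = "ZonationScheme",
                        plantedSupporters = "list", config = "list"))
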