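#' Configuration for the synthetic PAE data generator
#'
#' The generator emulates a binary areas-by-species matrix produced by
#' hierarchical vicariance: each clade of the true area tree carries planted
#' endemic (synapomorphic) species, a set of widespread species occurs in all
#' areas, singleton species occur in exactly one area, and independent
#' per-cell flips inject homoplasy noise.  The defaults (8 areas, 5 endemics
#' per clade, 10 widespread, 5 singletons, flip probability 0.05) give a
#' small, fast, non-trivial fixture.
#'
#' @param nAreas number of real areas (>= 4); ignored when `trueTree` given.
#' @param trueTree optional rooted binary `phylo` over the areas; `NULL`
#'   draws a uniform random rooted topology.
#' @param endemicsPerClade planted endemic species per non-root clade (>= 0).
#' @param nWidespread species present in all real areas (>= 0).
#' @param nSingleton species present in exactly one uniformly chosen area.
#' @param flipProbability per-cell flip noise in \[0, 0.5).
#' @param seed integer seed.
#' @param rootLabel label of the appended hypothetical root area.
#' @return validated list of class `pae_sim_config`.
#' @export
simulationConfig <- function(nAreas = 8L, trueTree = NULL,
                             endemicsPerClade = 5L, nWidespread = 10L,
                             nSingleton = 5L, flipProbability = 0.05,
                             seed = 20200812L, rootLabel = "ROOT") {
  if (!is.null(trueTree)) {
    stopifnot(inherits(trueTree, "phylo"))
    nAreas <- length(trueTree$tip.label)
  }
  if (nAreas < 4L) stop("config error: at least 4 areas required")
  if (flipProbability < 0 || flipProbability >= 0.5)
    stop("config error: flipProbability must lie in [0, 0.5)")
  if (endemicsPerClade < 0L || nWidespread < 0L || nSingleton < 0L)
    stop("config error: species counts must be non-negative")
  structure(list(nAreas = as.integer(nAreas), trueTree = trueTree,
                 endemicsPerClade = as.integer(endemicsPerClade),
                 nWidespread = as.integer(nWidespread),
                 nSingleton = as.integer(nSingleton),
                 flipProbability = flipProbability,
                 seed = as.integer(seed), rootLabel = rootLabel),
            class = "pae_sim_config")
}

#' Simulate a presence-absence matrix with known structure
#'
#' For every non-root clade of the (possibly drawn) true rooted tree the
#' generator emits `endemicsPerClade` species present exactly in that clade,
#' plus widespread and singleton species; each real-area cell is then flipped
#' independently with `flipProbability`.  The hypothetical root row is
#' appended all-zero and never touched by noise (it is an analytic device,
#' not data).  At flip probability 0 every planted endemic is a strict
#' synapomorphy of its clade and the search recovers the true topology
#' exactly.
#'
#' @param config a [simulationConfig()].
#' @return A [SimulationTruth-class]: the matrix (root included), the true
#'   rooted tree, its unrooted form with the root tip attached, the planted
#'   zonation, and the planted supporter map keyed by sorted clade areas.
#' @export
simulateMatrix <- function(config = simulationConfig()) {
  if (!inherits(config, "pae_sim_config"))
    stop("config must come from simulationConfig()")
  n <- config$nAreas
  labs <- sprintf("AR%02d", seq_len(n))
  .withSeed(config$seed, {
    tree <- config$trueTree
    if (is.null(tree)) tree <- randomAreaTree(labs, rooted = TRUE)
    else labs <- tree$tip.label
    nTip <- length(tree$tip.label)
    sets <- .nodeTipSets(tree$edge, nTip)
    rootNode <- .rootOfEdges(tree$edge)
    inner <- setdiff(sort(unique(tree$edge[, 1L])), rootNode)
    clades <- lapply(inner, function(v) sort(tree$tip.label[sets[[v]]]))

    cols <- list(); names_ <- character(0)
    planted <- list()
    for (j in seq_along(clades)) {
      cl <- clades[[j]]
      key <- .splitKey(cl)
      spNames <- sprintf("clade%02d_e%02d", j, seq_len(config$endemicsPerClade))
      planted[[key]] <- spNames
      for (s in spNames) {
        cols[[length(cols) + 1L]] <- as.integer(labs %in% cl)
        names_ <- c(names_, s)
      }
    }
    for (s in seq_len(config$nWidespread)) {
      cols[[length(cols) + 1L]] <- rep(1L, n)
      names_ <- c(names_, sprintf("widespread%02d", s))
    }
    for (s in seq_len(config$nSingleton)) {
      col <- rep(0L, n)
      col[sample.int(n, 1L)] <- 1L
      cols[[length(cols) + 1L]] <- col
      names_ <- c(names_, sprintf("singleton%02d", s))
    }
    if (!length(cols)) stop("config error: simulation produced no species")
    m <- do.call(cbind, cols)
    dimnames(m) <- list(labs, names_)
    if (config$flipProbability > 0) {
      flips <- matrix(stats::runif(length(m)) < config$flipProbability,
                      nrow(m), ncol(m))
      m <- abs(m - as.integer(flips))
      storage.mode(m) <- "integer"
    }
    m <- rbind(m, 0L)
    rownames(m)[n + 1L] <- config$rootLabel
    pam <- PresenceAbsenceMatrix(m, rootArea = config$rootLabel)

    # unrooted form: the root area tip attaches at the true tree's root node
    rootTip <- nTip + 1L
    edgeFull <- tree$edge
    edgeFull[edgeFull > nTip] <- edgeFull[edgeFull > nTip] + 1L
    rootNodeFull <- rootNode + 1L
    edgeFull <- rbind(edgeFull, c(rootNodeFull, rootTip))
    trueFull <- .internalToPhylo(edgeFull, c(tree$tip.label, config$rootLabel),
                                 root = rootNodeFull)
    attr(trueFull, "rootArea") <- config$rootLabel

    zoneTree <- tree
    zoneTree$node.label <- rep("100", tree$Nnode)
    attr(zoneTree, "paeRooted") <- TRUE
    trueZones <- extractZonation(zoneTree)

    new("SimulationTruth", pam = pam, trueTree = tree, trueTreeFull = trueFull,
        trueZones = trueZones, plantedSupporters = planted,
        config = unclass(config))
  })
}

.zonePartitionKey <- function(zs) {
  sort(vapply(zs@zones, function(z) .splitKey(z$areas), ""))
}

#' Recovery experiment: simulate, search, summarize
#'
#' Runs the pipeline simulate -> heuristic search -> strict consensus ->
#' zonation on one simulated data set and reports whether the true tree and
#' planted zones are recovered, together with split recall/precision against
#' the true (root-attached, unrooted) topology and the ensemble consistency
#' index.
#'
#' @param config a [simulationConfig()].
#' @param search a [searchConfig()].
#' @return list with `length`, `nTrees`, `splitRecall`, `splitPrecision`,
#'   `exactTopology`, `ci`, `zoneMatch`.
#' @export
recoveryExperiment <- function(config = simulationConfig(),
                               search = searchConfig()) {
  sim <- simulateMatrix(config)
  ref <- sim@config$rootLabel
  res <- heuristicSearch(sim@pam, search)
  cons <- strictConsensus(res, ref = ref)
  trueKeys <- .phyloSplits(sim@trueTreeFull, ref = ref)$keys
  consKeys <- .phyloSplits(cons, ref = ref)$keys
  recall <- if (length(trueKeys)) mean(trueKeys %in% consKeys) else 1
  precision <- if (length(consKeys)) mean(consKeys %in% trueKeys) else 1
  ci <- ensembleIndices(res, sim@pam)@ci
  rooted <- rootOn(cons, ref, prune = TRUE)
  zs <- extractZonation(rooted, sim@pam)
  list(length = res@length, nTrees = length(res@trees),
       splitRecall = recall, splitPrecision = precision,
       exactTopology = setequal(trueKeys, consKeys) &&
         length(consKeys) == length(trueKeys),
       ci = ci,
       zoneMatch = identical(.zonePartitionKey(zs),
                             .zonePartitionKey(sim@trueZones)))
}
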