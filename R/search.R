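#' Search configuration for heuristic parsimony search
#'
#' @param nReplicates number of random-addition-sequence replicates (>= 1).
#' @param seed integer seed driving addition orders and any other randomness.
#' @param maxTrees cap on the number of retained equal-length trees (>= 1);
#'   hitting the cap raises a truncation warning.
#' @param swap branch-swapping move: `"TBR"` (default), `"SPR"` or `"NNI"`.
#' @param keepEqual pool distinct topologies of equal best length?
#' @param steepest also use pooled equal-length trees as swap bases (slower,
#'   finds more equally parsimonious trees)?
#' @param deterministicAddition use the lexicographic area order for every
#'   replicate instead of seeded random orders.
#' @return A validated list of class `pae_search_config`.
#' @export
searchConfig <- function(nReplicates = 10L, seed = 1L, maxTrees = 1000L,
                         swap = c("TBR", "SPR", "NNI"), keepEqual = TRUE,
                         steepest = FALSE, deterministicAddition = FALSE) {
  swap <- match.arg(swap)
  if (maxTrees < 1L) stop("config error: maxTrees must be >= 1")
  if (nReplicates < 1L) stop("config error: nReplicates must be >= 1")
  structure(list(nReplicates = as.integer(nReplicates), seed = as.integer(seed),
                 maxTrees = as.integer(maxTrees), swap = swap,
                 keepEqual = isTRUE(keepEqual), steepest = isTRUE(steepest),
                 deterministicAddition = isTRUE(deterministicAddition)),
            class = "pae_search_config")
}

.swapFun <- function(swap) {
  switch(swap,
         TBR = .tbrNeighborsEdges,
         SPR = .sprNeighborsEdges,
         NNI = .nniNeighborsEdges,
         stop("unknown swap move: ", swap))
}

# greedy stepwise addition on internal edge matrices; `ord` is a permutation
# of tip ids.  Ties are broken by the first-encountered edge in the current
# row order of the edge matrix (new edges are appended on attachment, so the
# ordering is deterministic).
.stepwiseAdditionEdges <- function(codes, nTip, ord) {
  if (nTip < 3L) stop("stepwise addition needs at least 3 areas")
  edge <- cbind(rep(nTip + 1L, 3L), ord[1:3], deparse.level = 0)
  if (nTip == 3L) return(edge)
  for (k in 4:nTip) {
    tip <- ord[k]
    w <- nTip + k - 2L
    cand <- lapply(seq_len(nrow(edge)), function(i)
      .attachTipEdge(edge, i, tip, w))
    lens <- .fitchTotalManyC(cand, nTip, codes)
    edge <- cand[[which.min(lens)]]
  }
  edge
}

#' Stepwise-addition starting tree
#'
#' Builds a binary area tree greedily: the first three areas of `order` form
#' the unique unrooted 3-tip tree, then each subsequent area is attached to
#' the edge minimizing the Fitch length of the grown tree, ties going to the
#' first-encountered edge under the documented edge ordering.
#'
#' @param pam a [PresenceAbsenceMatrix-class] with at least 3 areas.
#' @param order area labels in addition order; `NULL` uses the matrix row
#'   order.
#' @return A `phylo` tree over all areas.
#' @export
stepwiseAddition <- function(pam, order = NULL) {
  labs <- areaLabels(pam)
  if (is.null(order)) order <- labs
  if (!setequal(order, labs) || length(order) != length(labs))
    stop("order must be a permutation of the area labels")
  codes <- .pamCodes(pam)
  edge <- .stepwiseAdditionEdges(codes, length(labs), match(order, labs))
  .internalToPhylo(edge, labs)
}

#' TBR neighborhood of a tree
#'
#' Bisects the tree on every edge, reduces both halves, and yields every
#' reconnection joining one edge of each half.  Neighbors are valid trees over
#' the same tip set, deduplicated by topology, and exclude the input tree.
#' Bisections on external edges contribute the single-tip pruning moves.
#'
#' @param tree a `phylo` with at least 4 tips.
#' @return list of `phylo` trees.
#' @export
tbrNeighbors <- function(tree) {
  if (length(tree$tip.label) < 4L) stop("TBR needs at least 4 tips")
  tree <- ape::unroot(tree)              # swaps operate on the unrooted shape
  labs <- tree$tip.label
  edge <- .phyloToInternal(tree, labs)
  lapply(.tbrNeighborsEdges(edge, length(labs)),
         .internalToPhylo, tipLabels = labs)
}

# one TBR/SPR/NNI ascent from a starting tree: first-improvement with a full
# restart of the sweep after each accepted move; equal-length neighbors are
# pooled on the final (improvement-free) sweep and, when `steepest`, also used
# as further swap bases
.swapToOptimum <- function(edge, nTip, codes, config) {
  swap <- .swapFun(config$swap)
  best <- sum(.fitchStepsC(edge, nTip, codes))
  pool <- list(edge)
  poolKeys <- .treeKeyEdges(edge, nTip)
  truncated <- FALSE
  nScored <- 0L
  sweep <- function(base) {
    # duplicates are tolerated here (cheap to score); topology keys are only
    # computed for equal-length pool candidates
    nbrs <- swap(base, nTip, dedup = FALSE)
    if (!length(nbrs)) return(NULL)
    lens <- .fitchTotalManyC(nbrs, nTip, codes)
    nScored <<- nScored + length(lens)
    list(nbrs = nbrs, lens = lens)
  }
  current <- edge
  repeat {
    sw <- sweep(current)
    if (is.null(sw)) break
    imp <- which(sw$lens < best)
    if (length(imp)) {
      current <- sw$nbrs[[imp[1L]]]
      best <- sw$lens[imp[1L]]
      pool <- list(current)
      poolKeys <- .treeKeyEdges(current, nTip)
      next
    }
    if (config$keepEqual) {
      for (i in which(sw$lens == best)) {
        k <- .treeKeyEdges(sw$nbrs[[i]], nTip)
        if (!(k %in% poolKeys)) {
          if (length(pool) >= config$maxTrees) { truncated <- TRUE; break }
          pool <- c(pool, sw$nbrs[i])
          poolKeys <- c(poolKeys, k)
        }
      }
    }
    break
  }
  if (config$steepest && config$keepEqual) {
    done <- character(0)
    repeat {
      todo <- which(!(poolKeys %in% done))
      if (!length(todo) || truncated) break
      i <- todo[1L]
      done <- c(done, poolKeys[i])
      sw <- sweep(pool[[i]])
      if (is.null(sw)) next
      imp <- which(sw$lens < best)
      if (length(imp)) {
        best <- sw$lens[imp[1L]]
        pool <- list(sw$nbrs[[imp[1L]]])
        poolKeys <- .treeKeyEdges(pool[[1L]], nTip)
        done <- character(0)
        next
      }
      for (j in which(sw$lens == best)) {
        k <- .treeKeyEdges(sw$nbrs[[j]], nTip)
        if (!(k %in% poolKeys)) {
          if (length(pool) >= config$maxTrees) { truncated <- TRUE; break }
          pool <- c(pool, sw$nbrs[j])
          poolKeys <- c(poolKeys, k)
        }
      }
    }
  }
  list(length = best, pool = pool, poolKeys = poolKeys,
       truncated = truncated, nScored = nScored)
}

# search engine over tip-state codes; uses the current RNG stream
.searchEngine <- function(codes, nTip, labs, config) {
  if (nTip < 3L || nrow(codes) < 1L)
    stop("search needs at least 3 areas and 1 species")
  bestLen <- Inf
  pool <- list(); poolKeys <- character(0)
  truncated <- FALSE
  repLog <- data.frame(replicate = integer(0), bestLength = integer(0),
                       treesScored = integer(0))
  for (i in seq_len(config$nReplicates)) {
    ord <- if (config$deterministicAddition) order(labs) else sample.int(nTip)
    start <- .stepwiseAdditionEdges(codes, nTip, ord)
    res <- .swapToOptimum(start, nTip, codes, config)
    repLog <- rbind(repLog, data.frame(replicate = i, bestLength = res$length,
                                       treesScored = res$nScored))
    if (res$length < bestLen) {
      bestLen <- res$length
      pool <- res$pool
      poolKeys <- res$poolKeys
      truncated <- res$truncated
    } else if (res$length == bestLen && config$keepEqual) {
      for (j in seq_along(res$pool)) {
        k <- res$poolKeys[j]
        if (!(k %in% poolKeys)) {
          if (length(pool) >= config$maxTrees) { truncated <- TRUE; break }
          pool <- c(pool, res$pool[j])
          poolKeys <- c(poolKeys, k)
        }
      }
    }
  }
  if (truncated)
    warning("equal-length tree pool truncated at maxTrees = ", config$maxTrees)
  list(length = as.integer(bestLen), pool = pool, log = repLog)
}

.makeParsimonyResult <- function(engineRes, codes, nTip, labs, config) {
  trees <- lapply(engineRes$pool, .internalToPhylo, tipLabels = labs)
  steps <- .fitchStepsC(engineRes$pool[[1L]], nTip, codes)
  names(steps) <- rownames(codes)
  new("ParsimonyResult", trees = trees, length = engineRes$length,
      perCharacterSteps = steps,
      searchLog = list(replicates = config$nReplicates, seed = config$seed,
                       swap = config$swap, perReplicate = engineRes$log,
                       truncated = length(trees) >= config$maxTrees))
}

#' Heuristic maximum-parsimony search
#'
#' Runs seeded random-addition-sequence replicates: each replicate builds a
#' stepwise-addition starting tree and applies repeated branch-swapping
#' sweeps (TBR by default), accepting strictly shorter trees until a full
#' sweep yields no improvement.  Equal-length distinct topologies are pooled
#' (capped at `maxTrees`) and replicates are merged at the best length found.
#' A designated root area participates as an ordinary taxon during the search.
#'
#' @param pam a [PresenceAbsenceMatrix-class] with >= 3 areas and >= 1 species.
#' @param config a [searchConfig()].
#' @return A [ParsimonyResult-class].
#' @examples
#' sim <- simulateMatrix(simulationConfig(nAreas = 6, flipProbability = 0))
#' heuristicSearch(sim@pam, searchConfig(nReplicates = 2, seed = 1))
#' @export
heuristicSearch <- function(pam, config = searchConfig()) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  if (!inherits(config, "pae_search_config"))
    stop("config must come from searchConfig()")
  labs <- areaLabels(pam)
  codes <- .pamCodes(pam)
  engineRes <- .withSeed(config$seed,
                         .searchEngine(codes, length(labs), labs, config))
  # rownames needed for per-character step names
  rownames(codes) <- speciesLabels(pam)
  .makeParsimonyResult(engineRes, codes, length(labs), labs, config)
}

#' Exhaustive maximum-parsimony search
#'
#' Scores every unrooted binary topology over the areas (there are
#' `(2n-5)!!`) and returns all optima with the exact minimum length.  Used as
#' the oracle against which the heuristic search is validated; refuses more
#' than 9 areas (135,135 topologies).
#'
#' @param pam a [PresenceAbsenceMatrix-class] with 3 to 9 areas.
#' @return A [ParsimonyResult-class] containing every optimal topology.
#' @export
exhaustiveSearch <- function(pam) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  labs <- areaLabels(pam)
  n <- length(labs)
  if (n > 9L)
    stop("size error: exhaustive search is limited to 9 areas (got ", n, ")")
  if (n < 3L) stop("search needs at least 3 areas")
  codes <- .pamCodes(pam)
  rownames(codes) <- speciesLabels(pam)
  topos <- .enumTopologies(n)
  lens <- .fitchTotalManyC(topos, n, codes)
  best <- min(lens)
  pool <- topos[lens == best]
  engineRes <- list(length = as.integer(best), pool = pool,
                    log = data.frame(replicate = 1L, bestLength = best,
                                     treesScored = length(topos)))
  cfg <- searchConfig(nReplicates = 1L, seed = 0L,
                      maxTrees = max(1L, length(pool)))
  .makeParsimonyResult(engineRes, codes, n, labs, cfg)
}

#' Root an area tree on a tip
#'
#' Places the root on the edge subtending `rootLabel` (the hypothetical root
#' area in a PAE analysis).  Support values carried as internal node labels
#' are re-attached to their splits.  With `prune = TRUE` the root tip is
#' removed for display while the induced rooted topology is preserved.
#' Rooting never changes the unrooted Fitch length.
#'
#' @param tree a `phylo`; internal node labels, when present, are treated as
#'   support values.
#' @param rootLabel tip label to root on.
#' @param prune drop the root tip after rooting?
#' @return A rooted `phylo` (attribute `paeRooted` set); when `prune = TRUE`
#'   the root area is no longer a tip.
#' @export
rootOn <- function(tree, rootLabel, prune = FALSE) {
  if (!rootLabel %in% tree$tip.label)
    stop("root label '", rootLabel, "' is not a tip of the tree")
  info <- .phyloSplits(tree, ref = rootLabel)
  allTips <- tree$tip.label
  keep <- if (prune) setdiff(allTips, rootLabel) else allTips
  clades <- info$sides
  supports <- info$supports
  if (!prune) {
    # the complement clade restores the binary shape below the root tip
    rest <- sort(setdiff(allTips, rootLabel))
    clades <- c(clades, list(rest))
    supports <- c(supports, NA_real_)
  } else {
    drop <- vapply(clades, function(s) setequal(s, keep), TRUE)
    clades <- clades[!drop]
    supports <- supports[!drop]
  }
  out <- .buildCladeTree(clades, sort(keep), supports)
  attr(out, "paeRooted") <- TRUE
  attr(out, "rootArea") <- if (prune) NA_character_ else rootLabel
  out
}
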