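.splitKey <- function(side) paste(sort(side), collapse = "+")

# nontrivial splits of a phylo as label sets on the side excluding `ref`,
# with any internal-node labels carried along as supports
.phyloSplits <- function(phy, ref = NULL) {
  labs <- phy$tip.label
  nTip <- length(labs)
  if (is.null(ref)) ref <- sort(labs)[1L]
  if (!ref %in% labs) stop("reference tip '", ref, "' not in tree")
  edge <- phy$edge
  sets <- .nodeTipSets(edge, nTip)
  nodeLab <- phy$node.label
  sides <- list(); supports <- numeric(0); keys <- character(0)
  inner <- unique(edge[, 2L][edge[, 2L] > nTip])
  for (v in inner) {
    side <- labs[sets[[v]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > nTip - 2L) next
    key <- .splitKey(side)
    if (key %in% keys) next
    sup <- NA_real_
    if (!is.null(nodeLab)) {
      lab <- nodeLab[v - nTip]
      if (!is.null(lab) && !is.na(lab) && nzchar(lab))
        sup <- suppressWarnings(as.numeric(lab))
    }
    sides <- c(sides, list(sort(side)))
    supports <- c(supports, sup)
    keys <- c(keys, key)
  }
  list(sides = sides, keys = keys, supports = supports, ref = ref)
}

.nwkLabel <- function(x) {
  ifelse(grepl("[ ,:;()\\[\\]']", x), paste0("'", gsub("'", "_", x), "'"), x)
}

# build a rooted (possibly multifurcating) tree from a laminar family of
# clades over `allTips`; `supports` become internal node labels
.buildCladeTree <- function(clades, allTips, supports = NULL) {
  nC <- length(clades)
  if (is.null(supports)) supports <- rep(NA_real_, nC)
  if (nC) {
    keys <- vapply(clades, .splitKey, "")
    keepIdx <- !duplicated(keys)
    clades <- clades[keepIdx]; supports <- supports[keepIdx]
    nC <- length(clades)
    ord <- order(-lengths(clades), vapply(clades, .splitKey, ""))
    clades <- clades[ord]; supports <- supports[ord]
    for (i in seq_len(nC)) {
      for (j in seq_len(i - 1L)) {
        inter <- length(intersect(clades[[i]], clades[[j]]))
        if (inter && inter != length(clades[[i]]))
          stop("internal error: incompatible clades cannot form a tree")
      }
    }
  }
  # parent of clade i = smallest strictly containing clade (0 = root)
  parent <- integer(nC)
  for (i in seq_len(nC)) {
    parent[i] <- 0L
    for (j in rev(seq_len(i - 1L)))
      if (all(clades[[i]] %in% clades[[j]])) { parent[i] <- j; break }
  }
  tipParent <- vapply(allTips, function(t) {
    p <- 0L
    for (j in rev(seq_len(nC))) if (t %in% clades[[j]]) { p <- j; break }
    p
  }, 0L)
  fmtSupport <- function(s) {
    if (is.na(s)) "" else if (abs(s - round(s)) < 1e-9) as.character(round(s))
    else formatC(s, digits = 1, format = "f")
  }
  build <- function(i) {
    kidClades <- which(parent == i)
    kidTips <- sort(allTips[tipParent == i])
    parts <- c(vapply(kidClades, build, ""), .nwkLabel(kidTips))
    lab <- if (i == 0L) "" else fmtSupport(supports[i])
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  txt <- paste0(build(0L), ";")
  out <- ape::read.tree(text = txt)
  attr(out, "splitSupports") <- stats::setNames(supports,
                                                vapply(clades, .splitKey, ""))
  out
}

#' Bipartitions (splits) of an area tree
#'
#' One split per internal edge; trivial splits (a single tip on either side)
#' are excluded, so an unrooted binary tree over n tips yields n - 3 splits.
#' Splits are canonicalized by storing the side excluding `ref` (default: the
#' tree's `rootArea` attribute when set, otherwise the alphabetically first
#' tip), so differently drawn encodings of one topology give identical sets.
#'
#' @param tree a `phylo`.
#' @param ref reference tip label excluded from the stored sides.
#' @return A [BipartitionSet-class].
#' @export
bipartitions <- function(tree, ref = NULL) {
  if (is.null(ref)) {
    ra <- attr(tree, "rootArea")
    if (!is.null(ra) && !is.na(ra) && ra %in% tree$tip.label) ref <- ra
  }
  info <- .phyloSplits(tree, ref = ref)
  new("BipartitionSet", splits = info$sides, keys = info$keys,
      ref = info$ref, nTrees = 1L)
}

.treeListOf <- function(trees) {
  if (is(trees, "ParsimonyResult")) return(trees@trees)
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  stopifnot(is.list(trees), all(vapply(trees, inherits, TRUE, "phylo")))
  trees
}

.checkSameTips <- function(treeList) {
  tips <- treeList[[1L]]$tip.label
  for (t in treeList[-1L])
    if (!setequal(t$tip.label, tips) || length(t$tip.label) != length(tips))
      stop("trees must share an identical tip set")
  tips
}

.refFor <- function(treeList, ref) {
  if (!is.null(ref)) return(ref)
  for (t in treeList) {
    ra <- attr(t, "rootArea")
    if (!is.null(ra) && !is.na(ra) && ra %in% t$tip.label) return(ra)
  }
  sort(treeList[[1L]]$tip.label)[1L]
}

# split frequency bookkeeping over a list of trees
.splitCounts <- function(treeList, ref) {
  counts <- numeric(0)
  sides <- list()
  for (t in treeList) {
    info <- .phyloSplits(t, ref = ref)
    for (i in seq_along(info$keys)) {
      k <- info$keys[i]
      if (is.na(counts[k])) { counts[k] <- 0; sides[[k]] <- info$sides[[i]] }
      counts[k] <- counts[k] + 1
    }
  }
  list(counts = counts, sides = sides)
}

#' Strict consensus of area trees
#'
#' Retains exactly the splits present in every input tree; disagreement
#' collapses into polytomies.
#'
#' @param trees a list of `phylo`, a `multiPhylo`, or a
#'   [ParsimonyResult-class].
#' @param ref reference tip for split canonicalization (defaults to the
#'   designated root area when available).
#' @return A `phylo` (multifurcating where trees disagree).
#' @export
strictConsensus <- function(trees, ref = NULL) {
  treeList <- .treeListOf(trees)
  tips <- .checkSameTips(treeList)
  ref <- .refFor(treeList, ref)
  sc <- .splitCounts(treeList, ref)
  keep <- names(sc$counts)[sc$counts == length(treeList)]
  out <- .buildCladeTree(sc$sides[keep], sort(tips))
  attr(out, "rootArea") <- ref
  out
}

#' Majority-rule consensus of area trees
#'
#' Retains the splits whose frequency strictly exceeds `cutoff` percent; with
#' a cutoff of at least 50 the retained splits are mutually compatible by the
#' majority guarantee.  Frequencies (observed count / n trees x 100) are
#' attached as internal node labels and as the `splitFrequencies` attribute.
#'
#' @inheritParams strictConsensus
#' @param cutoff percentage in \[50, 100).
#' @return A `phylo` with frequency node labels.
#' @export
majorityRuleConsensus <- function(trees, cutoff = 50, ref = NULL) {
  if (cutoff < 50) stop("config error: cutoff must be >= 50")
  treeList <- .treeListOf(trees)
  tips <- .checkSameTips(treeList)
  ref <- .refFor(treeList, ref)
  sc <- .splitCounts(treeList, ref)
  freq <- 100 * sc$counts / length(treeList)
  keep <- names(freq)[freq > cutoff]
  out <- .buildCladeTree(sc$sides[keep], sort(tips), supports = freq[keep])
  attr(out, "rootArea") <- ref
  attr(out, "splitFrequencies") <- freq[keep]
  out
}

#' Nonparametric bootstrap support for the PAE tree
#'
#' Resamples species (characters) with replacement to the original character
#' count, reruns the heuristic search on each pseudo-matrix (with reduced
#' within-replicate effort by default), and records split frequencies.  When a
#' replicate yields several equally parsimonious trees their splits receive
#' fractional weights summing to one per replicate, avoiding over-counting.
#' Supports are mapped onto the strict consensus of the full-data most
#' parsimonious trees (matching the convention of annotating the final
#' parsimony tree), or onto the bootstrap majority-rule tree with
#' `supportOn = "bootstrap-majority"`.
#'
#' @param pam a [PresenceAbsenceMatrix-class]; a designated root area is
#'   retained in every replicate.
#' @param nReplicates number of bootstrap replicates (>= 1).
#' @param config full-data [searchConfig()].
#' @param replicateConfig within-replicate search settings; default is
#'   `config` reduced to one addition replicate.
#' @param seed integer seed for resampling and replicate searches.
#' @param supportOn where to annotate supports.
#' @return A [BootstrapSummary-class]; node supports are integers 0-100.
#' @export
bootstrapSupport <- function(pam, nReplicates = 100L, config = searchConfig(),
                             replicateConfig = NULL, seed = 1L,
                             supportOn = c("mpt-consensus", "bootstrap-majority")) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  supportOn <- match.arg(supportOn)
  if (nReplicates < 1L) stop("config error: nReplicates must be >= 1")
  if (is.null(replicateConfig)) {
    replicateConfig <- config
    replicateConfig$nReplicates <- 1L
  }
  labs <- areaLabels(pam)
  nTip <- length(labs)
  codes <- .pamCodes(pam)
  nChar <- nrow(codes)
  ref <- if (!is.na(rootArea(pam))) rootArea(pam) else sort(labs)[1L]

  full <- heuristicSearch(pam, config)
  cons <- strictConsensus(full, ref = ref)

  freq <- numeric(0); sides <- list()
  repLens <- numeric(nReplicates)
  .withSeed(seed, {
    for (b in seq_len(nReplicates)) {
      cols <- sample.int(nChar, nChar, replace = TRUE)
      res <- .searchEngine(codes[cols, , drop = FALSE], nTip, labs,
                           replicateConfig)
      repLens[b] <- res$length
      k <- length(res$pool)
      repCounts <- list()
      for (tr in res$pool) {
        sets <- .nodeTipSets(tr, nTip)
        for (v in unique(tr[, 2L][tr[, 2L] > nTip])) {
          side <- labs[sets[[v]]]
          if (ref %in% side) side <- setdiff(labs, side)
          if (length(side) < 2L || length(side) > nTip - 2L) next
          ky <- .splitKey(side)
          if (is.null(repCounts[[ky]])) {
            repCounts[[ky]] <- 0
            if (is.null(sides[[ky]])) sides[[ky]] <- sort(side)
          }
          repCounts[[ky]] <- repCounts[[ky]] + 1
        }
      }
      for (ky in names(repCounts)) {
        if (is.na(freq[ky])) freq[ky] <- 0
        freq[ky] <- freq[ky] + repCounts[[ky]] / k
      }
    }
  })
  pct <- 100 * freq / nReplicates

  target <- if (supportOn == "mpt-consensus") {
    info <- .phyloSplits(cons, ref = ref)
    .buildCladeTree(info$sides, sort(labs),
                    supports = ifelse(is.na(pct[info$keys]), 0,
                                      round(pct[info$keys])))
  } else {
    keep <- names(pct)[pct > 50]
    .buildCladeTree(sides[keep], sort(labs), supports = round(pct[keep]))
  }
  attr(target, "rootArea") <- ref
  new("BootstrapSummary", nReplicates = as.integer(nReplicates),
      splitFrequencies = pct, splitSides = sides[names(pct)],
      consensus = target, seed = as.integer(seed),
      replicateLengths = repLens, fullSearch = full)
}

#' Write a split-frequency table
#'
#' Tab-separated table with one row per observed split: the sorted tip list
#' (joined with "+") and its bootstrap percentage.
#'
#' @param bs a [BootstrapSummary-class].
#' @param path output file.
#' @return The table, invisibly.
#' @export
writeSplitTable <- function(bs, path) {
  stopifnot(is(bs, "BootstrapSummary"))
  ord <- order(-bs@splitFrequencies, names(bs@splitFrequencies))
  tab <- data.frame(split = names(bs@splitFrequencies)[ord],
                    percentage = round(bs@splitFrequencies[ord], 2),
                    row.names = NULL)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
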