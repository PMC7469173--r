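# state-set codes for the C kernel: 1 = {0}, 2 = {1}, 3 = {0,1} (ambiguous)
.pamCodes <- function(pam) {
  v <- pam@values
  codes <- ifelse(is.na(v), 3L, v + 1L)
  t(codes)                               # nChar x nTip
}

#' Fitch parsimony length of an area tree
#'
#' Scores every species (binary character) on the tree by the Fitch state-set
#' pass: a post-order sweep takes the intersection of the child state sets
#' when non-empty, otherwise their union at the cost of one step.  The kernel
#' applies Hartigan's majority rule at each node, which coincides with Fitch
#' on bifurcating nodes for two states and stays exact on multifurcations, so
#' consensus trees and the basal trichotomy of unrooted trees are scored
#' correctly.  Ambiguous (`NA`) cells carry the full state set \{0,1\}.  The
#' length is invariant under re-rooting.
#'
#' @param tree a `phylo` tree whose tips are exactly the areas of `pam`.
#' @param pam a [PresenceAbsenceMatrix-class].
#' @return list with `length` (integer total steps) and `perCharacterSteps`
#'   (named integer, steps per species).
#' @examples
#' sim <- simulateMatrix(simulationConfig(nAreas = 6, flipProbability = 0))
#' tr <- randomAreaTree(areaLabels(sim@pam), seed = 1)
#' fitchLength(tr, sim@pam)$length
#' @export
fitchLength <- function(tree, pam) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"), inherits(tree, "phylo"))
  edge <- .phyloToInternal(tree, areaLabels(pam))
  codes <- .pamCodes(pam)
  steps <- .fitchStepsC(edge, length(areaLabels(pam)), codes)
  names(steps) <- speciesLabels(pam)
  list(length = sum(steps), perCharacterSteps = steps)
}

#' Minimum possible steps of a binary character
#'
#' The minimum number of changes of a binary character over all trees:
#' 0 for a constant character (ignoring ambiguous cells), otherwise 1.
#'
#' @param column 0/1/`NA` vector over at least 2 areas.
#' @return integer.
#' @export
minSteps <- function(column) {
  obs <- unique(column[!is.na(column)])
  if (length(obs) <= 1L) 0L else 1L
}

#' Maximum possible steps of a binary character
#'
#' The parsimony length of a binary character on its worst-case tree:
#' `min(#0s, #1s)` (achieved on a caterpillar alternating the states);
#' ambiguous cells are ignored as they can always adopt the favourable state.
#'
#' @inheritParams minSteps
#' @return integer.
#' @export
maxSteps <- function(column) {
  min(sum(column == 0L, na.rm = TRUE), sum(column == 1L, na.rm = TRUE))
}
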