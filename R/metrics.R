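# adjusted Fisher-Pearson sample skewness g1
.g1Skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NaN)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

# parsimony-informative binary character: both states in at least two areas
.isInformative <- function(column) {
  sum(column == 0L, na.rm = TRUE) >= 2L && sum(column == 1L, na.rm = TRUE) >= 2L
}

#' Ensemble fit indices (CI, RI, RC, HI)
#'
#' Computes the ensemble consistency index CI = sum(m)/sum(s), retention
#' index RI = (sum(g) - sum(s))/(sum(g) - sum(m)), rescaled consistency
#' RC = CI * RI and homoplasy index HI = 1 - CI, where for every species m is
#' the minimum steps over all trees ([minSteps()]), s the observed Fitch steps
#' on the designated tree, and g the steps on the worst tree ([maxSteps()]).
#' Constant characters (0/0 contributions) are always excluded; by default
#' parsimony-uninformative variable characters (singleton presences, for
#' which m = s = g) are included, mirroring the common parsimony-software
#' convention, and can be dropped with `includeUninformative = FALSE`.
#'
#' When `x` holds several equally parsimonious trees the indices are computed
#' on the first and verified identical across all; any divergence is recorded
#' in the `perTree` slot with a message.
#'
#' @param x a [ParsimonyResult-class] or a single `phylo` tree.
#' @param pam the [PresenceAbsenceMatrix-class] that was searched.
#' @param includeUninformative keep variable but parsimony-uninformative
#'   characters in the sums?
#' @return An [EnsembleIndices-class].
#' @export
ensembleIndices <- function(x, pam, includeUninformative = TRUE) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  trees <- if (is(x, "ParsimonyResult")) x@trees else list(x)
  v <- pam@values
  m <- apply(v, 2L, minSteps)
  g <- apply(v, 2L, maxSteps)
  keep <- m > 0L                                   # drop constant characters
  if (!includeUninformative)
    keep <- keep & apply(v, 2L, .isInformative)
  sPerTree <- vapply(trees, function(tr)
    sum(fitchLength(tr, pam)$perCharacterSteps[keep]), 0)
  s1 <- fitchLength(trees[[1L]], pam)$perCharacterSteps
  sm <- sum(m[keep]); sg <- sum(g[keep]); ss <- sum(s1[keep])
  if (ss == 0 && sm > 0)
    stop("internal error: zero observed steps with variable characters")
  if (sm == 0) {
    warning("no variable characters; indices are undefined")
    ci <- ri <- rc <- hi <- NA_real_
  } else {
    ci <- sm / ss
    ri <- if (sg > sm) (sg - ss) / (sg - sm) else {
      warning("all retained characters have g = m; RI undefined")
      NaN
    }
    rc <- ci * ri
    hi <- 1 - ci
  }
  perTree <- data.frame(tree = seq_along(trees), s = sPerTree)
  if (length(unique(sPerTree)) > 1L)
    message("equally parsimonious trees differ in retained-character sums; ",
            "see the perTree slot")
  new("EnsembleIndices", ci = ci, ri = ri, rc = rc, hi = hi,
      sums = c(m = sm, s = ss, g = sg), nCharUsed = sum(keep),
      perTree = perTree)
}

#' Length distribution over uniform random topologies
#'
#' Draws `n` labeled unrooted binary topologies uniformly (sequential
#' insertion at uniformly chosen edges), scores each with Fitch parsimony and
#' reports the mean, standard deviation and adjusted Fisher-Pearson sample
#' skewness g1 = n/((n-1)(n-2)) * sum(((x - mean)/sd)^3).  A strongly
#' negative g1 indicates hierarchical signal in the matrix.  All lengths lie
#' within \[sum(m), sum(g)\].
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param n number of random trees (>= 3).
#' @param seed integer seed.
#' @return A [RandomTreeDistribution-class]; `g1` is `NaN` with a warning for
#'   a degenerate (zero-variance) distribution.
#' @export
randomTreeLengths <- function(pam, n = 1000L, seed = 1L) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"), n >= 3L)
  labs <- areaLabels(pam)
  nTip <- length(labs)
  codes <- .pamCodes(pam)
  lens <- .withSeed(seed, {
    topos <- replicate(n, .randomTopologyEdges(nTip), simplify = FALSE)
    .fitchTotalManyC(topos, nTip, codes)
  })
  g1 <- .g1Skewness(lens)
  if (is.nan(g1))
    warning("degenerate length distribution (zero variance); skewness undefined")
  new("RandomTreeDistribution", lengths = as.integer(lens),
      nTrees = as.integer(n), mean = mean(lens), sd = stats::sd(lens),
      g1 = g1, seed = as.integer(seed))
}
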