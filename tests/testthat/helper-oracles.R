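# Independent oracles and fixture builders shared across the suite.

# minimum-mutation score of one binary character by exhaustive enumeration of
# all internal-state assignments (independent of the Fitch implementation)
bruteForceSteps <- function(tree, column) {
  labs <- tree$tip.label
  n <- length(labs)
  edge <- tree$edge
  internal <- sort(unique(edge[edge > n]))
  best <- Inf
  for (mask in 0:(2^length(internal) - 1L)) {
    st <- integer(max(edge))
    st[seq_len(n)] <- column[labs]
    st[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    best <- min(best, sum(st[edge[, 1]] != st[edge[, 2]]))
  }
  best
}

# random binary matrix with no empty area (guaranteeing class validity)
randomBinaryPam <- function(nAreas, nChar, p = 0.4,
                            areas = sprintf("t%02d", seq_len(nAreas))) {
  v <- matrix(rbinom(nAreas * nChar, 1L, p), nAreas, nChar,
              dimnames = list(areas, sprintf("s%03d", seq_len(nChar))))
  v[cbind(seq_len(nAreas), sample.int(nChar, nAreas, replace = TRUE))] <- 1L
  PresenceAbsenceMatrix(v)
}

# presence-absence matrix from explicit 0/1 pattern strings, one per area
pamFromStrings <- function(patterns, species = NULL, rootArea = character(0)) {
  rows <- lapply(patterns, function(s)
    as.integer(strsplit(s, "")[[1]]))
  v <- do.call(rbind, rows)
  rownames(v) <- names(patterns)
  colnames(v) <- species %||% sprintf("sp%02d", seq_len(ncol(v)))
  PresenceAbsenceMatrix(v, rootArea = rootArea)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# four-tip trees written by hand
tree4 <- function(newick = "((A,B),(C,D));") ape::read.tree(text = newick)

topologyKey <- function(tree) {
  bp <- bipartitions(tree, ref = sort(tree$tip.label)[1])
  paste(sort(bp@keys), collapse = ";")
}

occurrenceCSV <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("species,family,area,source", lines), path)
  path
}
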