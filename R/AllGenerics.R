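#' @name accessors
#' @title Accessors for PAEzone containers
#' @param x an object.
#' @description Accessor generics for the S4 containers: area and species
#'   labels, the 0/1 value matrix, the designated root area, the family map,
#'   parsimony trees and lengths, split frequencies and zonation tables.
NULL

#' @rdname accessors
#' @export
setGeneric("areaLabels", function(x) standardGeneric("areaLabels"))
#' @rdname accessors
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))
#' @rdname accessors
#' @export
setGeneric("paValues", function(x) standardGeneric("paValues"))
#' @rdname accessors
#' @export
setGeneric("rootArea", function(x) standardGeneric("rootArea"))
#' @rdname accessors
#' @export
setGeneric("familyOf", function(x) standardGeneric("familyOf"))
#' @rdname accessors
#' @export
setGeneric("mptTrees", function(x) standardGeneric("mptTrees"))
#' @rdname accessors
#' @export
setGeneric("treeLength", function(x) standardGeneric("treeLength"))
#' @rdname accessors
#' @export
setGeneric("perCharacterSteps", function(x) standardGeneric("perCharacterSteps"))
#' @rdname accessors
#' @export
setGeneric("splitFrequencies", function(x) standardGeneric("splitFrequencies"))
#' @rdname accessors
#' @export
setGeneric("consensusTree", function(x) standardGeneric("consensusTree"))
#' @rdname accessors
#' @export
setGeneric("zones", function(x) standardGeneric("zones"))
#' @rdname accessors
#' @export
setGeneric("zoneTable", function(x) standardGeneric("zoneTable"))
#' @rdname accessors
#' @export
setGeneric("aoeClades", function(x) standardGeneric("aoeClades"))

#' @rdname accessors
#' @export
setMethod("areaLabels", "PresenceAbsenceMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("speciesLabels", "PresenceAbsenceMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("paValues", "PresenceAbsenceMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("rootArea", "PresenceAbsenceMatrix",
          function(x) if (length(x@rootArea)) x@rootArea else NA_character_)
#' @rdname accessors
#' @export
setMethod("familyOf", "PresenceAbsenceMatrix", function(x) x@familyOf)

#' @rdname accessors
#' @export
setMethod("mptTrees", "ParsimonyResult", function(x) x@trees)
#' @rdname accessors
#' @export
setMethod("treeLength", "ParsimonyResult", function(x) x@length)
#' @rdname accessors
#' @export
setMethod("perCharacterSteps", "ParsimonyResult", function(x) x@perCharacterSteps)

#' @rdname accessors
#' @export
setMethod("splitFrequencies", "BootstrapSummary", function(x) x@splitFrequencies)
#' @rdname accessors
#' @export
setMethod("consensusTree", "BootstrapSummary", function(x) x@consensus)

#' @rdname accessors
#' @export
setMethod("zones", "ZonationScheme", function(x) x@zones)
#' @rdname accessors
#' @export
setMethod("zoneTable", "ZonationScheme", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("aoeClades", "ZonationScheme", function(x) x@aoes)

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  v <- object@values
  cat("PresenceAbsenceMatrix:", nrow(v), "areas x", ncol(v), "species\n")
  if (length(object@rootArea))
    cat("  hypothetical root area:", object@rootArea, "\n")
  if (anyNA(v)) cat(" ", sum(is.na(v)), "ambiguous (?) cells\n")
  occ <- rowSums(v == 1L, na.rm = TRUE)
  occ <- occ[setdiff(names(occ), object@rootArea)]
  if (length(occ))
    cat("  richness range:", min(occ), "-", max(occ), "\n")
  invisible(object)
})

setMethod("show", "ParsimonyResult", function(object) {
  cat("ParsimonyResult:", length(object@trees),
      if (length(object@trees) == 1L) "tree" else "trees",
      "of length", object@length, "\n")
  if (isTRUE(object@searchLog$truncated))
    cat("  (equal-length tree pool truncated at maxTrees)\n")
  invisible(object)
})

setMethod("show", "EnsembleIndices", function(object) {
  cat(sprintf("Ensemble indices over %d characters:\n", object@nCharUsed))
  cat(sprintf("  CI = %.3f  RI = %.3f  RC = %.3f  HI = %.3f\n",
              object@ci, object@ri, object@rc, object@hi))
  cat(sprintf("  sums: m = %d, s = %d, g = %d\n",
              as.integer(object@sums["m"]), as.integer(object@sums["s"]),
              as.integer(object@sums["g"])))
  invisible(object)
})

setMethod("show", "RandomTreeDistribution", function(object) {
  cat(sprintf("Random-tree length distribution (n = %d): mean = %.2f, sd = %.2f, g1 = %.3f\n",
              object@nTrees, object@mean, object@sd, object@g1))
  invisible(object)
})

setMethod("show", "BipartitionSet", function(object) {
  cat("BipartitionSet:", length(object@splits), "nontrivial splits (ref:",
      object@ref, ")\n")
  invisible(object)
})

setMethod("show", "BootstrapSummary", function(object) {
  cat("BootstrapSummary:", object@nReplicates, "replicates,",
      length(object@splitFrequencies), "splits observed\n")
  invisible(object)
})

setMethod("show", "ZonationScheme", function(object) {
  nsub <- sum(vapply(object@zones, function(z) length(z$subzones), 1L))
  cat("ZonationScheme:", length(object@zones), "zones,", nsub, "subzones,",
      length(object@aoes), "areas of endemism\n")
  for (z in object@zones)
    cat(sprintf("  %s: %s%s\n", z$label, paste(z$areas, collapse = ", "),
                if (length(z$subzones))
                  paste0("  [subzones: ",
                         paste(vapply(z$subzones,
                                      function(s) paste(s, collapse = "+"), ""),
                               collapse = "; "), "]")
                else ""))
  invisible(object)
})

setMethod("show", "RichnessSummary", function(object) {
  cat("RichnessSummary:", object@totalSpecies, "species over",
      length(object@perAreaRichness), "areas\n")
  cat(sprintf("  richness: min %d (%s), median %.1f, max %d (%s)\n",
              object@minRichness, paste(object@minAreas, collapse = ","),
              object@medianRichness,
              object@maxRichness, paste(object@maxAreas, collapse = ",")))
  invisible(object)
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@pam@values), "areas (incl. root) x",
      ncol(object@pam@values), "species; flip probability",
      object@config$flipProbability, "\n")
  invisible(object)
})
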