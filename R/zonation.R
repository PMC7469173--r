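# rooted-tree helpers -------------------------------------------------------

.assertRooted <- function(tree) {
  if (!isTRUE(attr(tree, "paeRooted")) && !ape::is.rooted(tree))
    stop("a rooted tree is required (see rootOn())")
}

# prune the designated root tip when still present
.pruneRootTip <- function(tree) {
  ra <- attr(tree, "rootArea")
  if (!is.null(ra) && !is.na(ra) && ra %in% tree$tip.label)
    tree <- rootOn(tree, ra, prune = TRUE)
  tree
}

# label tip sets of all internal nodes of a rooted tree (top node included)
.rootedCladeSets <- function(tree) {
  nTip <- length(tree$tip.label)
  sets <- .nodeTipSets(tree$edge, nTip)
  inner <- sort(unique(c(tree$edge[, 1L])))
  lapply(stats::setNames(inner, inner),
         function(v) tree$tip.label[sets[[v]]])
}

.nonRootArea <- function(pam) setdiff(areaLabels(pam), pam@rootArea)

#' Species supporting a clade of areas
#'
#' Strict supporters are the synapomorphic species: present in every member
#' area of the clade and absent from all non-member areas (the hypothetical
#' root never counts).  Lenient supporters are present in every member and in
#' at most `leniency` areas outside.  Both lists come directly from the
#' matrix, not from ancestral-state reconstructions; strict supporters are
#' always a subset of the lenient ones.  Ambiguous (`NA`) cells count as
#' absences.
#'
#' @param tree a rooted `phylo` over the areas.
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param clade character vector of areas; must be a clade of `tree`.
#' @param leniency maximum outside occurrences for the lenient list.
#' @return list with `clade`, `strict` and `lenient` species vectors.
#' @export
supportingSpecies <- function(tree, pam, clade, leniency = 1L) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  .assertRooted(tree)
  tree <- .pruneRootTip(tree)
  sets <- .rootedCladeSets(tree)
  isClade <- any(vapply(sets, setequal, TRUE, y = clade)) ||
    (length(clade) == 1L && clade %in% tree$tip.label)
  if (!isClade)
    stop("the given area set is not a clade of the tree: ",
         paste(clade, collapse = ", "))
  .supportersOf(pam, clade, leniency)
}

.supportersOf <- function(pam, clade, leniency = 1L) {
  v <- pam@values
  outside <- setdiff(.nonRootArea(pam), clade)
  inAll <- colSums(v[clade, , drop = FALSE] == 1L, na.rm = TRUE) == length(clade)
  outCount <- colSums(v[outside, , drop = FALSE] == 1L, na.rm = TRUE)
  sp <- colnames(v)
  list(clade = sort(clade),
       strict = sp[inAll & outCount == 0L],
       lenient = sp[inAll & outCount <= leniency])
}

#' Detect areas of endemism on the area cladogram
#'
#' An area of endemism (AOE) is a clade of at least two areas supported by at
#' least `minSupporters` strict synapomorphic species (present in every
#' member and nowhere else).  Clades containing the hypothetical root and the
#' all-area clade are excluded.  Results are ordered largest clade first.
#'
#' @param tree a rooted `phylo` (root tip may still be present).
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param minSupporters minimum number of strict supporting species
#'   (default 2, the usual PAE criterion).
#' @return list of AOEs, each with `areas` and `species`; monotone
#'   non-increasing in `minSupporters`.
#' @export
detectAOEs <- function(tree, pam, minSupporters = 2L) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  .assertRooted(tree)
  tree <- .pruneRootTip(tree)
  sets <- .rootedCladeSets(tree)
  allTips <- tree$tip.label
  keep <- vapply(sets, function(s)
    length(s) >= 2L && length(s) < length(allTips), TRUE)
  cands <- unique(lapply(sets[keep], sort))
  out <- list()
  for (cl in cands) {
    sup <- .supportersOf(pam, cl)
    if (length(sup$strict) >= minSupporters)
      out[[length(out) + 1L]] <- list(areas = cl, species = sup$strict)
  }
  ord <- order(-vapply(out, function(a) length(a$areas), 1L),
               vapply(out, function(a) .splitKey(a$areas), ""))
  out[ord]
}

#' Species widespread across the areas
#'
#' Species present in at least `ceiling(minFraction * nAreas)` areas (the
#' hypothetical root excluded), sorted by occupancy then name.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param minFraction occupancy fraction in (0, 1].
#' @return named integer vector of occupancies, names = species.
#' @export
widespreadSpecies <- function(pam, minFraction = 0.9) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"), minFraction > 0, minFraction <= 1)
  areas <- .nonRootArea(pam)
  thr <- ceiling(minFraction * length(areas))
  occ <- colSums(pam@values[areas, , drop = FALSE] == 1L, na.rm = TRUE)
  occ <- occ[occ >= thr]
  occ[order(-occ, names(occ))]
}

.zoneLabel <- function(i) {
  if (i <= 26L) LETTERS[i] else paste0("Z", i)
}

#' Extract a zone/subzone scheme from the rooted area cladogram
#'
#' Formalizes the nesting rule "areas at the ends of the same branch combine
#' and nest into the areas on superior branches": traversing from the root,
#' every maximal clade with support at least `supportFloor` and at least
#' `minZoneSize` areas becomes a zone; a tip hanging beside a qualifying
#' sibling clade nests into the first such zone in traversal order; tips
#' absorbed by no qualifying clade become singleton zones.  Within a zone,
#' cherries (sister tip pairs strictly inside the zone's clade) become
#' subzones and the remaining tips attach directly.  Internal nodes without a
#' numeric support label are treated as fully supported.  Zone labels are
#' assigned A, B, C, ... in traversal order.
#'
#' @param tree a rooted, support-annotated `phylo` (from [rootOn()] or a
#'   [bootstrapSupport()] consensus); the root tip is pruned automatically.
#' @param pam optional [PresenceAbsenceMatrix-class]; when given, areas of
#'   endemism with their supporting species are attached via [detectAOEs()].
#' @param supportFloor minimum support for a clade to found a zone
#'   (default 70).
#' @param minZoneSize minimum clade size for a zone (default 2).
#' @param minSupporters passed to [detectAOEs()].
#' @return A [ZonationScheme-class]; zones always partition the non-root
#'   areas and subzones lie within their parent zone.
#' @export
extractZonation <- function(tree, pam = NULL, supportFloor = 70,
                            minZoneSize = 2L, minSupporters = 2L) {
  .assertRooted(tree)
  tree <- .pruneRootTip(tree)
  nTip <- length(tree$tip.label)
  labs <- tree$tip.label
  edge <- tree$edge
  kids <- split(edge[, 2L], edge[, 1L])
  sets <- .nodeTipSets(edge, nTip)
  root <- .rootOfEdges(edge)
  support <- function(v) {
    if (is.null(tree$node.label)) return(100)
    s <- suppressWarnings(as.numeric(tree$node.label[v - nTip]))
    if (is.na(s)) 100 else s
  }
  qualifies <- function(v) {
    length(sets[[v]]) >= minZoneSize && support(v) >= supportFloor
  }
  # returns list(zones = list of list(node, attached), loose = tip ids);
  # loose tips nest into the first zone collected at the node where one exists
  collect <- function(v) {
    zs <- list(); loose <- integer(0)
    for (ch in kids[[as.character(v)]]) {
      if (ch <= nTip) loose <- c(loose, ch)
      else if (qualifies(ch)) zs <- c(zs, list(list(node = ch, attached = integer(0))))
      else {
        r <- collect(ch)
        zs <- c(zs, r$zones)
        loose <- c(loose, r$loose)
      }
    }
    if (length(zs) && length(loose)) {
      zs[[1L]]$attached <- c(zs[[1L]]$attached, loose)
      loose <- integer(0)
    }
    list(zones = zs, loose = loose)
  }
  res <- collect(root)
  # cherries strictly inside a clade become subzones
  cherriesIn <- function(v) {
    out <- list()
    for (w in setdiff(.componentNodesBelow(edge, v), v)) {
      if (w > nTip) {
        k <- kids[[as.character(w)]]
        if (length(k) == 2L && all(k <= nTip))
          out[[length(out) + 1L]] <- sort(labs[k])
      }
    }
    out
  }
  zonesOut <- list()
  tab <- data.frame(area = character(0), zone = character(0),
                    subzone = character(0))
  i <- 0L
  addRow <- function(area, zone, sub) {
    tab <<- rbind(tab, data.frame(area = area, zone = zone, subzone = sub))
  }
  for (z in res$zones) {
    i <- i + 1L
    lab <- .zoneLabel(i)
    cladeAreas <- sort(labs[sets[[z$node]]])
    attached <- sort(labs[z$attached])
    cherries <- cherriesIn(z$node)
    subzones <- list()
    for (ch in cherries) {
      if (length(ch) < length(cladeAreas)) {
        subzones[[paste0(lab, length(subzones) + 1L)]] <- ch
      }
    }
    for (a in cladeAreas) {
      sub <- ""
      for (sl in names(subzones)) if (a %in% subzones[[sl]]) sub <- sl
      addRow(a, lab, sub)
    }
    for (a in attached) addRow(a, lab, "")
    zonesOut[[length(zonesOut) + 1L]] <-
      list(label = lab, areas = c(cladeAreas, attached),
           cladeAreas = cladeAreas, subzones = subzones, singleton = FALSE)
  }
  unplaced <- sort(labs[res$loose])
  for (a in unplaced) {
    i <- i + 1L
    lab <- .zoneLabel(i)
    zonesOut[[length(zonesOut) + 1L]] <-
      list(label = lab, areas = a, cladeAreas = a,
           subzones = list(), singleton = TRUE)
    addRow(a, lab, "")
  }
  covered <- sort(unlist(lapply(zonesOut, `[[`, "areas"), use.names = FALSE))
  if (!identical(covered, sort(labs)))
    stop("internal error: zones do not partition the areas")
  aoes <- list()
  if (!is.null(pam))
    aoes <- detectAOEs(tree, pam, minSupporters = minSupporters)
  new("ZonationScheme", zones = zonesOut, aoes = aoes,
      unplaced = unplaced, table = tab)
}

# all nodes in the subtree rooted at v (tips and internals)
.componentNodesBelow <- function(edge, v) {
  kids <- split(edge[, 2L], edge[, 1L])
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, x)
    k <- kids[[as.character(x)]]
    if (!is.null(k)) stack <- c(stack, k)
  }
  out
}

#' Write a zonation scheme to JSON and TSV
#'
#' @param zs a [ZonationScheme-class].
#' @param jsonPath,tsvPath output paths (`NULL` to skip either).
#' @return list with the JSON-ready structure, invisibly.
#' @export
writeZonation <- function(zs, jsonPath = NULL, tsvPath = NULL) {
  stopifnot(is(zs, "ZonationScheme"))
  obj <- list(
    zones = lapply(zs@zones, function(z)
      list(label = z$label, areas = z$areas, subzones = z$subzones,
           singleton = z$singleton)),
    areas_of_endemism = lapply(zs@aoes, function(a)
      list(areas = a$areas, supporting_species = a$species)),
    unplaced = zs@unplaced)
  if (!is.null(jsonPath))
    jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(tsvPath))
    utils::write.table(zs@table, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(obj)
}
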