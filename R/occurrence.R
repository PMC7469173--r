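#' Default butterfly family list
#'
#' The five-family system for butterflies: Papilionidae, Pieridae,
#' Nymphalidae, Lycaenidae, Hesperiidae.
#'
#' @return character vector.
#' @export
defaultFamilies <- function() {
  c("Papilionidae", "Pieridae", "Nymphalidae", "Lycaenidae", "Hesperiidae")
}

.squishWhitespace <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Load occurrence records from delimited text
#'
#' Reads species occurrence records (species, family, area code, source) from
#' a delimited file.  All rows are loaded; rows failing validation (empty
#' species or area, family outside the configured list) are reported with
#' their file line numbers in the `problems` attribute and a warning.
#' Duplicate (species, area) rows are kept; deduplication happens in
#' [buildMatrix()].
#'
#' @param path CSV (or other delimited) file with a header.
#' @param schema named character mapping the record fields `species`,
#'   `family`, `area`, `source` to column names in the file; `source` is
#'   optional.
#' @param families allowed family names.
#' @param sep field separator.
#' @return data.frame with columns `species`, `family`, `area`, `source` and
#'   attribute `problems` (data.frame `line`, `field`, `message`).
#' @export
loadOccurrences <- function(path,
                            schema = c(species = "species", family = "family",
                                       area = "area", source = "source"),
                            families = defaultFamilies(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty-input error: no records in ", path)
  need <- c("species", "family", "area")
  for (f in need) {
    col <- schema[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop("schema error: column '", col %||% f, "' (field '", f,
           "') missing from ", path)
  }
  srcCol <- schema[["source"]]
  rec <- data.frame(
    species = .squishWhitespace(raw[[schema[["species"]]]]),
    family = trimws(raw[[schema[["family"]]]]),
    area = trimws(raw[[schema[["area"]]]]),
    source = if (!is.null(srcCol) && srcCol %in% names(raw))
      raw[[srcCol]] else NA_character_,
    stringsAsFactors = FALSE)
  problems <- data.frame(line = integer(0), field = character(0),
                         message = character(0))
  flag <- function(rows, field, msg) {
    if (any(rows))
      problems <<- rbind(problems,
                         data.frame(line = which(rows) + 1L, field = field,
                                    message = msg))
  }
  flag(!nzchar(rec$species), "species", "empty species name")
  flag(!nzchar(rec$area), "area", "empty area code")
  flag(!rec$family %in% families, "family",
       paste0("family not in configured list (",
              paste(families, collapse = ", "), ")"))
  if (nrow(problems))
    warning(nrow(problems), " record(s) failed validation; see attr(x, 'problems')")
  attr(rec, "problems") <- problems
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a presence-absence matrix from occurrence records
#'
#' Assigns cell (area, species) = 1 when at least one record matches,
#' 0 otherwise; duplicate records collapse to a single 1 (the operation is
#' idempotent under record duplication).  Species columns follow
#' first-appearance order in the records; species names are merged by exact
#' match after whitespace normalization (no taxonomic synonym resolution).
#'
#' @param records data.frame from [loadOccurrences()] (columns `species`,
#'   `area`, optionally `family`).
#' @param areas ordered area-code vector; every record's area must appear in
#'   it.
#' @return A [PresenceAbsenceMatrix-class].
#' @examples
#' rec <- data.frame(species = c("sp1", "sp1", "sp2"),
#'                   family = "Pieridae", area = c("A", "B", "A"))
#' paValues(buildMatrix(rec, c("A", "B")))
#' @export
buildMatrix <- function(records, areas) {
  if (!length(areas)) stop("areas must be non-empty")
  if (anyDuplicated(areas)) stop("duplicated area codes")
  species <- .squishWhitespace(records$species)
  recArea <- records$area
  unknown <- sort(unique(recArea[!recArea %in% areas]))
  if (length(unknown))
    stop("unknown-area error: record area(s) not in the area list: ",
         paste(unknown, collapse = ", "))
  spLevels <- unique(species)              # first-appearance order
  m <- matrix(0L, length(areas), length(spLevels),
              dimnames = list(areas, spLevels))
  m[cbind(match(recArea, areas), match(species, spLevels))] <- 1L
  fam <- character(0)
  if (!is.null(records$family)) {
    first <- !duplicated(species)
    fam <- stats::setNames(records$family[first], species[first])
  }
  PresenceAbsenceMatrix(m, familyOf = fam)
}

#' Append the hypothetical root area
#'
#' Adds an artificial area with no species (an all-zero row) and designates
#' it as the root taxon used to root the area cladogram.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param label label for the new area; must not collide with an existing
#'   area.
#' @return A [PresenceAbsenceMatrix-class] with one extra all-zero row.
#' @export
addHypotheticalRoot <- function(pam, label = "ROOT") {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  if (label %in% areaLabels(pam))
    stop("label collision: area '", label, "' already exists")
  v <- rbind(pam@values, 0L)
  rownames(v)[nrow(v)] <- label
  PresenceAbsenceMatrix(v, rootArea = label, familyOf = pam@familyOf)
}

#' Richness summary of a presence-absence matrix
#'
#' Per-area species counts (the hypothetical root, when present, is
#' excluded), per-area family fractions when a family map exists, the overall
#' and per-family totals, the median richness (mean of the two central values
#' for an even number of areas), the extreme areas, and per-group summaries
#' for an optional area grouping (e.g. east/west of a dividing line).
#' Ambiguous (`NA`) cells count as absences.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param groupings optional named character mapping areas to group labels.
#' @return A [RichnessSummary-class].
#' @export
richnessSummary <- function(pam, groupings = NULL) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  v <- pam@values
  if (length(pam@rootArea))
    v <- v[setdiff(rownames(v), pam@rootArea), , drop = FALSE]
  rich <- as.integer(rowSums(v == 1L, na.rm = TRUE))
  names(rich) <- rownames(v)
  famFrac <- matrix(numeric(0), 0, 0)
  famTot <- integer(0)
  if (length(pam@familyOf)) {
    fams <- sort(unique(pam@familyOf))
    famOfCol <- pam@familyOf[colnames(v)]
    famFrac <- matrix(0, nrow(v), length(fams),
                      dimnames = list(rownames(v), fams))
    for (f in fams) {
      cols <- which(!is.na(famOfCol) & famOfCol == f)
      famFrac[, f] <- rowSums(v[, cols, drop = FALSE] == 1L, na.rm = TRUE)
    }
    famTot <- stats::setNames(as.integer(table(factor(famOfCol, levels = fams))),
                              fams)
    nz <- rich > 0L
    famFrac[nz, ] <- famFrac[nz, , drop = FALSE] / rich[nz]
  }
  med <- stats::median(rich)
  mn <- min(rich); mx <- max(rich)
  groupSummaries <- data.frame(group = character(0), nAreas = integer(0),
                               median = numeric(0), min = integer(0),
                               max = integer(0))
  if (!is.null(groupings)) {
    g <- groupings[names(rich)]
    for (lab in sort(unique(g[!is.na(g)]))) {
      r <- rich[!is.na(g) & g == lab]
      groupSummaries <- rbind(groupSummaries,
                              data.frame(group = lab, nAreas = length(r),
                                         median = stats::median(r),
                                         min = min(r), max = max(r)))
    }
  }
  new("RichnessSummary",
      perAreaRichness = rich, familyFractions = famFrac,
      totalSpecies = ncol(v), perFamilyTotals = famTot,
      medianRichness = med,
      minAreas = names(rich)[rich == mn], minRichness = mn,
      maxAreas = names(rich)[rich == mx], maxRichness = mx,
      groupSummaries = groupSummaries)
}
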