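#' Read a presence-absence matrix from NEXUS
#'
#' Parses a NEXUS DATA (or CHARACTERS) block with `DATATYPE=STANDARD` and
#' symbols 0/1 via [ape::read.nexus.data()], validates the declared NTAX and
#' NCHAR against the matrix body, and records "?" cells as ambiguous (`NA`).
#'
#' @param path NEXUS file.
#' @param rootArea optional label to designate as the hypothetical root.
#' @return A [PresenceAbsenceMatrix-class].
#' @export
readNexusMatrix <- function(path, rootArea = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !grepl("^#NEXUS", txt[1], ignore.case = TRUE))
    stop("parse error in ", path, ", line 1: missing #NEXUS header")
  dimLine <- grep("DIMENSIONS", txt, ignore.case = TRUE)[1]
  ntax <- nchar_ <- NA_integer_
  if (!is.na(dimLine)) {
    m <- regmatches(txt[dimLine],
                    regexec("NTAX\\s*=\\s*([0-9]+)", txt[dimLine],
                            ignore.case = TRUE))[[1]]
    if (length(m) == 2L) ntax <- as.integer(m[2])
    m <- regmatches(txt[dimLine],
                    regexec("NCHAR\\s*=\\s*([0-9]+)", txt[dimLine],
                            ignore.case = TRUE))[[1]]
    if (length(m) == 2L) nchar_ <- as.integer(m[2])
  }
  dat <- tryCatch(ape::read.nexus.data(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (!is.na(ntax) && length(dat) != ntax)
    stop("parse error in ", path, ", line ", dimLine, ": NTAX=", ntax,
         " but the matrix body has ", length(dat), " rows")
  lens <- lengths(dat)
  if (length(unique(lens)) != 1L)
    stop("parse error in ", path, ": rows differ in character count")
  if (!is.na(nchar_) && lens[1] != nchar_)
    stop("parse error in ", path, ", line ", dimLine, ": NCHAR=", nchar_,
         " but rows have ", lens[1], " characters")
  vals <- do.call(rbind, lapply(dat, function(r) {
    r <- tolower(r)
    bad <- !(r %in% c("0", "1", "?", "n", "-"))
    if (any(bad))
      stop("parse error in ", path, ": symbol '", r[bad][1],
           "' outside SYMBOLS \"01\" / MISSING=?")
    r[r %in% c("?", "n", "-")] <- NA_character_
    as.integer(r)
  }))
  rownames(vals) <- names(dat)
  colnames(vals) <- paste0("char", seq_len(ncol(vals)))
  PresenceAbsenceMatrix(vals, rootArea = rootArea)
}

#' Write a presence-absence matrix as NEXUS
#'
#' Emits a `DATA` block with `DATATYPE=STANDARD SYMBOLS="01" MISSING=?`;
#' ambiguous (`NA`) cells become "?", and labels containing spaces are
#' quoted.  Species names are not representable in the standard block and are
#' dropped ([writeMatrixCSV()] preserves them).
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeNexusMatrix <- function(pam, path) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  v <- pam@values
  lab <- rownames(v)
  lab <- ifelse(grepl("[[:space:]]", lab), paste0("'", lab, "'"), lab)
  rows <- apply(v, 1L, function(r)
    paste(ifelse(is.na(r), "?", as.character(r)), collapse = ""))
  pad <- formatC(lab, width = max(nchar(lab)), flag = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS",
               "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(v), ncol(v)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX",
               paste0("    ", pad, "  ", rows),
               "  ;",
               "END;"), con)
  invisible(path)
}

#' Read/write a presence-absence matrix as CSV
#'
#' The CSV carries an `area` column followed by one 0/1 column per species;
#' ambiguous cells are "?" on disk.
#'
#' @param path CSV file.
#' @param rootArea optional root-area designation on read.
#' @return [PresenceAbsenceMatrix-class] (read) or `path` invisibly (write).
#' @export
readMatrixCSV <- function(path, rootArea = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"area" %in% names(df)) stop("parse error in ", path, ": no 'area' column")
  areas <- df$area
  vals <- as.matrix(df[setdiff(names(df), "area")])
  vals[vals == "?"] <- NA
  storage.mode(vals) <- "integer"
  rownames(vals) <- areas
  PresenceAbsenceMatrix(vals, rootArea = rootArea)
}

#' @rdname readMatrixCSV
#' @param pam a [PresenceAbsenceMatrix-class].
#' @export
writeMatrixCSV <- function(pam, path) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  v <- pam@values
  out <- data.frame(area = rownames(v), check.names = FALSE)
  body <- apply(v, 2L, function(col) ifelse(is.na(col), "?", as.character(col)))
  out <- cbind(out, as.data.frame(body, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an area grouping configuration
#'
#' Key-value text mapping area codes to group labels (climate zone,
#' east/west side of a dividing line, ...).  The file is tab- or
#' comma-separated with a header whose first column is `area`; lines starting
#' with `#` are comments.  A default 22-ecoregion configuration for Yunnan
#' ships as `system.file("extdata", "yunnan_ecoregions_synthetic.tsv",
#' package = "PAEzone")`.
#'
#' @param path configuration file.
#' @param column which grouping column to return; `NULL` returns the whole
#'   data.frame.
#' @return named character (area -> group) or the full data.frame.
#' @export
readAreaGroups <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"area" %in% names(df))
    stop("parse error in ", path, ": no 'area' column")
  if (is.null(column)) return(df)
  if (!column %in% names(df))
    stop("no grouping column '", column, "' in ", path)
  stats::setNames(as.character(df[[column]]), df$area)
}

#' Write an area tree as Newick
#'
#' Thin wrapper over [ape::write.tree()]; integer support values present as
#' node labels are preserved.
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAreaTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read an area tree from Newick
#'
#' @param path Newick file.
#' @param rootArea optional tip label recorded as the designated root.
#' @return A `phylo`; internal node labels are kept as support values.
#' @export
readAreaTree <- function(path, rootArea = NULL) {
  tr <- ape::read.tree(path)
  if (!is.null(rootArea)) attr(tr, "rootArea") <- rootArea
  tr
}
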