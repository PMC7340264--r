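## Text I/O for merged and unmerged reflection data.
##
## Merged dialect: '#'-comment lines; a `# CELL a b c alpha beta gamma`
## header and a `# KIND F|I` header; data lines `h k l value sigma flag`.
## Unmerged dialect: XDS-ASCII style; '!'-prefixed headers (cell optionally
## in `!UNIT_CELL_CONSTANTS=`); data lines `h k l I sigI`.

#' Read merged reflection data
#'
#' Parses the whitespace-separated merged text format: comment lines start
#' with `#`; a `# CELL a b c alpha beta gamma` header is required; a
#' `# KIND F` or `# KIND I` header declares whether the value column holds
#' amplitudes or intensities (default "F"). Data lines are
#' `h k l value sigma flag` with an integer CCP4-style free flag. The
#' number of free-flag sets is inferred as `max(flag) + 1`.
#'
#' @param path File path.
#' @param formatHint Optional "F" or "I" overriding a missing KIND header.
#' @return A [MergedSet-class].
#' @export
readMerged <- function(path, formatHint = NULL) {
  lines <- readLines(path)
  cell <- NULL; kind <- formatHint
  for (ln in grep("^\\s*#", lines, value = TRUE)) {
    tok <- strsplit(trimws(sub("^\\s*#", "", ln)), "\\s+")[[1]]
    if (length(tok) >= 7 && toupper(tok[1]) == "CELL")
      cell <- unitCellNew(as.numeric(tok[2]), as.numeric(tok[3]), as.numeric(tok[4]),
                          as.numeric(tok[5]), as.numeric(tok[6]), as.numeric(tok[7]))
    if (length(tok) >= 2 && toupper(tok[1]) == "KIND") kind <- toupper(tok[2])
  }
  if (is.null(cell)) stop("missing '# CELL a b c alpha beta gamma' header in ", path)
  if (is.null(kind)) kind <- "F"
  if (!kind %in% c("F", "I")) stop("KIND must be 'F' or 'I' in ", path)
  isData <- !grepl("^\\s*(#|$)", lines)
  if (!any(isData)) stop("no reflections in ", path)
  rows <- which(isData)
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(fields) < 6L)
  if (length(bad))
    stop("line ", rows[bad[1]], ": expected 'h k l value sigma flag'")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = length(fields[[1]]),
              byrow = TRUE)
  if (anyNA(m[, 1:6])) {
    bad <- rows[which(rowSums(is.na(m[, 1:6, drop = FALSE])) > 0)[1]]
    stop("line ", bad, ": non-numeric field")
  }
  if (any(m[, 1:3] != round(m[, 1:3])))
    stop("line ", rows[which(rowSums(m[, 1:3] != round(m[, 1:3])) > 0)[1]],
         ": Miller indices must be integers")
  if (any(m[, 6] != round(m[, 6])))
    stop("line ", rows[which(m[, 6] != round(m[, 6]))[1]],
         ": free flag must be an integer")
  if (any(m[, 5] <= 0))
    stop("line ", rows[which(m[, 5] <= 0)[1]], ": sigma must be positive")
  hkl <- m[, 1:3, drop = FALSE]; storage.mode(hkl) <- "integer"
  new("MergedSet", cell = cell, hkl = friedelReduce(hkl), value = m[, 4],
      sigma = m[, 5], flag = as.integer(m[, 6]), kind = kind,
      flagCount = as.integer(max(m[, 6]) + 1))
}

#' Write merged reflection data
#'
#' Writes the merged text format read by [readMerged()]. A write-read
#' round trip reproduces all records exactly in their decimal text
#' representation.
#'
#' @param x A [MergedSet-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeMerged <- function(x, path) {
  hdr <- c(sprintf("# CELL %.6g %.6g %.6g %.6g %.6g %.6g",
                   x@cell@a, x@cell@b, x@cell@c, x@cell@alpha, x@cell@beta, x@cell@gamma),
           paste("# KIND", x@kind),
           "# h k l value sigma flag")
  body <- sprintf("%d %d %d %.10g %.10g %d",
                  x@hkl[, 1], x@hkl[, 2], x@hkl[, 3], x@value, x@sigma, x@flag)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read unmerged intensities (XDS-ASCII-style text)
#'
#' Lines starting with `!` are headers; data lines with at least five
#' whitespace-separated fields are parsed as `h k l I sigma(I)`. The cell
#' is taken from a `!UNIT_CELL_CONSTANTS= a b c alpha beta gamma` header
#' when present, otherwise the `cell` argument is required. Observations
#' with sigma <= 0 are dropped with a message reporting the count;
#' negative intensities are retained.
#'
#' @param path File path.
#' @param cell Optional [UnitCell-class] used when the file has no cell
#'   header.
#' @param label Provenance label (default the file name).
#' @return An [UnmergedSet-class].
#' @export
readUnmerged <- function(path, cell = NULL, label = basename(path)) {
  lines <- readLines(path)
  hdr <- grep("^!", lines, value = TRUE)
  cc <- grep("UNIT_CELL_CONSTANTS", hdr, value = TRUE)
  if (length(cc)) {
    tok <- as.numeric(strsplit(trimws(sub(".*=", "", cc[1])), "\\s+")[[1]])
    if (length(tok) < 6 || anyNA(tok[1:6]))
      stop("malformed !UNIT_CELL_CONSTANTS= header in ", path)
    cell <- unitCellNew(tok[1], tok[2], tok[3], tok[4], tok[5], tok[6])
  }
  if (is.null(cell))
    stop("no unit cell: neither !UNIT_CELL_CONSTANTS= in ", path,
         " nor a 'cell' argument")
  dat <- lines[!grepl("^\\s*(!|$)", lines)]
  fields <- strsplit(trimws(dat), "\\s+")
  fields <- fields[lengths(fields) >= 5L]
  if (!length(fields)) stop("no observations in ", path)
  m <- t(vapply(fields, function(f) as.numeric(f[1:5]), numeric(5)))
  if (anyNA(m)) stop("non-numeric observation fields in ", path)
  drop <- m[, 5] <= 0
  if (any(drop))
    message("readUnmerged: dropped ", sum(drop), " observation(s) with sigma <= 0")
  m <- m[!drop, , drop = FALSE]
  hkl <- m[, 1:3, drop = FALSE]; storage.mode(hkl) <- "integer"
  new("UnmergedSet", cell = cell, hkl = hkl, intensity = m[, 4],
      sigma = m[, 5], label = label)
}

#' Write unmerged intensities (XDS-ASCII-style text)
#'
#' @param x An [UnmergedSet-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeUnmerged <- function(x, path) {
  hdr <- c("!FORMAT=XDS_ASCII_STYLE",
           sprintf("!UNIT_CELL_CONSTANTS= %.6g %.6g %.6g %.6g %.6g %.6g",
                   x@cell@a, x@cell@b, x@cell@c, x@cell@alpha, x@cell@beta, x@cell@gamma),
           "!ITEM_H=1 !ITEM_K=2 !ITEM_L=3 !ITEM_IOBS=4 !ITEM_SIGMA(IOBS)=5")
  body <- sprintf("%d %d %d %.10g %.10g",
                  x@hkl[, 1], x@hkl[, 2], x@hkl[, 3], x@intensity, x@sigma)
  writeLines(c(hdr, body, "!END_OF_DATA"), path)
  invisible(path)
}

#' Construct a merged set in memory
#'
#' @param cell A [UnitCell-class].
#' @param hkl Integer (n x 3) matrix of Miller indices (Friedel-reduced
#'   internally).
#' @param value Amplitudes or intensities, per `kind`.
#' @param sigma Positive standard uncertainties.
#' @param flag Integer free flags.
#' @param kind "F" (amplitudes) or "I" (intensities).
#' @param nFlagSets Number of free-flag sets; default `max(flag) + 1`.
#' @return A [MergedSet-class].
#' @export
mergedSet <- function(cell, hkl, value, sigma, flag, kind = "F",
                      nFlagSets = max(flag) + 1L) {
  storage.mode(hkl) <- "integer"
  new("MergedSet", cell = cell, hkl = friedelReduce(hkl),
      value = as.numeric(value), sigma = as.numeric(sigma),
      flag = as.integer(flag), kind = kind, flagCount = as.integer(nFlagSets))
}

#' Construct an unmerged set in memory
#'
#' @param cell A [UnitCell-class].
#' @param hkl Integer (n x 3) matrix, one row per observation.
#' @param intensity Observed intensities.
#' @param sigma Positive standard uncertainties.
#' @param label Provenance label.
#' @return An [UnmergedSet-class].
#' @export
unmergedSet <- function(cell, hkl, intensity, sigma, label = "unmerged") {
  storage.mode(hkl) <- "integer"
  new("UnmergedSet", cell = cell, hkl = hkl, intensity = as.numeric(intensity),
      sigma = as.numeric(sigma), label = label)
}
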