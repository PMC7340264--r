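## Report bundle: CSV tables and a single-page HTML summary.

.writeCsv <- function(df, path) {
  cols <- names(df)
  fmt <- function(v) {
    if (is.numeric(v)) fmtNum(v)
    else ifelse(is.na(v), "", as.character(v))
  }
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

.htmlTable <- function(df, caption) {
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
  cells <- vapply(seq_len(nrow(df)), function(i)
    paste0("<tr><td>", paste(esc(ifelse(is.na(unlist(df[i, ])), "",
      vapply(df[i, ], function(v) if (is.numeric(v)) sprintf("%.4g", v)
             else as.character(v), character(1)))), collapse = "</td><td>"),
      "</td></tr>"), character(1))
  paste0("<h2>", caption, "</h2>\n<table border='1' cellspacing='0'>\n<tr><th>",
         paste(esc(names(df)), collapse = "</th><th>"), "</th></tr>\n",
         paste(cells, collapse = "\n"), "\n</table>\n")
}

#' Write the report bundle for a ladder or cross-validation result
#'
#' Emits `steps.csv` (per-step paired comparisons with the Rgap-at-A
#' curve), `shells.csv` (per-step per-shell R/CC statistics with CC* and
#' the high-Rwork flag), `merging.csv` when merging statistics are
#' attached, per-step refined models as PDB files, and a single-page
#' `report.html` presenting the same tables. CSV output is written at
#' full precision with fixed formatting, so reruns at a fixed seed are
#' byte-identical.
#'
#' @param result A [LadderResult-class] or [CrossValResult-class].
#' @param dir Output directory (created if needed).
#' @param writeModels Write per-step PDB models (default TRUE; ladder
#'   results only).
#' @return Character vector of the files written, invisibly.
#' @export
writeReports <- function(result, dir, writeModels = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  sections <- character(0)
  if (is(result, "LadderResult")) {
    f <- file.path(dir, "steps.csv"); .writeCsv(result@steps, f); files <- c(files, f)
    sections <- c(sections, .htmlTable(result@steps,
      sprintf("Paired comparisons (start %.3f A, free set %d)",
              result@startRes, result@freeSet)))
    if (nrow(result@shellStats)) {
      f <- file.path(dir, "shells.csv"); .writeCsv(result@shellStats, f)
      files <- c(files, f)
      sections <- c(sections, .htmlTable(result@shellStats,
        "Per-shell statistics (CCwork/CCfree vs CC*; Rwork flagged above 0.42)"))
    }
    if (!is.null(result@merging)) {
      f <- file.path(dir, "merging.csv"); .writeCsv(result@merging, f)
      files <- c(files, f)
      sections <- c(sections, .htmlTable(result@merging, "Merging statistics"))
    }
    if (writeModels && length(result@models)) {
      for (i in seq_along(result@models)) {
        f <- file.path(dir, sprintf("model_step%02d_%.3fA.pdb", i - 1L,
                                    result@models[[i]]@cutoff))
        writePDB(result@models[[i]]@model, f)
        files <- c(files, f)
      }
    }
  } else if (is(result, "CrossValResult")) {
    f <- file.path(dir, "steps.csv"); .writeCsv(result@summary, f); files <- c(files, f)
    sections <- c(sections, .htmlTable(result@summary,
      sprintf("Complete cross-validation over %d free sets (SEM = SD/sqrt(k))",
              result@k)))
    for (q in seq_along(result@results)) {
      f <- file.path(dir, sprintf("steps_set%02d.csv", q - 1L))
      .writeCsv(result@results[[q]]@steps, f); files <- c(files, f)
    }
  } else stop("unsupported result type")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Paired-refinement report</title></head><body>",
            "<h1>Paired-refinement report</h1>",
            "<p>The tables report; the resolution-cutoff decision stays with the user.</p>",
            sections, "</body></html>")
  f <- file.path(dir, "report.html"); writeLines(html, f); files <- c(files, f)
  invisible(files)
}
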