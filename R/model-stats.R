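## Model-vs-data agreement: scaling, R values, Rgap, CCwork/CCfree, the
## random-data R flag, and the matched-resolution paired comparison.

#' Least-squares amplitude scale
#'
#' `k = sum(|Fo| |Fc|) / sum(|Fc|^2)`, fitted on the work set only and
#' applied to both sets.
#'
#' @param fo Observed amplitudes.
#' @param fc Calculated amplitudes.
#' @return Scalar scale k.
#' @export
lsScale <- function(fo, fc) {
  if (length(fo) != length(fc) || length(fo) == 0)
    stop("fo and fc must be nonempty and of equal length")
  den <- sum(fc^2)
  if (den == 0) stop("all calculated amplitudes are zero")
  sum(fo * fc) / den
}

#' Crystallographic R value
#'
#' `R = sum | |Fo| - k |Fc| | / sum |Fo|`.
#'
#' @param fo Observed amplitudes.
#' @param fc Calculated amplitudes.
#' @param k Scale applied to fc.
#' @return Scalar R.
#' @export
rValue <- function(fo, fc, k) {
  if (length(fo) != length(fc) || length(fo) == 0)
    stop("fo and fc must be nonempty and of equal length")
  den <- sum(fo)
  if (den == 0) stop("sum of observed amplitudes is zero")
  sum(abs(fo - k * fc)) / den
}

.pearsonOrNA <- function(a, b) {
  if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Model-vs-data agreement report
#'
#' Splits the merged data into work (`flag != freeSet`) and free
#' (`flag == freeSet`) sets, fits the amplitude scale on the work set
#' only, and reports overall and per-shell Rwork, Rfree,
#' `Rgap = Rfree - Rwork`, and CCwork/CCfree. CC values are Pearson
#' correlations between experimental and calculated *intensities*
#' (squared scaled amplitudes). Shells with fewer than three reflections
#' in a set carry NA for that CC. Any shell whose Rwork exceeds
#' `rFlagLevel` (default 0.42, the R value of a perfect model against
#' random acentric data) is flagged in the report — a warning annotation,
#' never a filter.
#'
#' @param merged A [MergedSet-class] (already at, or truncated to, the
#'   reporting cutoff).
#' @param calc A [CalcSet-class] covering every index in `merged`.
#' @param shells A [ShellScheme-class].
#' @param freeSet Free-flag value treated as the test set (default 0).
#' @param rFlagLevel Rwork level flagged in the shell table (default 0.42).
#' @return An [AgreementReport-class].
#' @export
agreementReport <- function(merged, calc, shells, freeSet = 0L,
                            rFlagLevel = 0.42) {
  fcIdx <- match(friedelKey(merged@hkl), friedelKey(calc@hkl))
  if (anyNA(fcIdx)) {
    miss <- merged@hkl[which(is.na(fcIdx))[1], ]
    stop(sprintf("no calculated structure factor for reflection (%d %d %d)",
                 miss[1], miss[2], miss[3]))
  }
  fo <- obsAmplitudes(merged)
  fc <- Mod(calc@fc)[fcIdx]
  free <- merged@flag == freeSet
  if (!any(!free)) stop("empty work set")
  k <- lsScale(fo[!free], fc[!free])
  io <- fo^2                      # observed intensities (|Fo|^2)
  ic <- (k * fc)^2                # calculated intensities
  d <- dSpacing(merged@cell, merged@hkl)
  idx <- shellAssign(shells, d)

  statsFor <- function(sel) {
    if (!any(sel)) return(c(r = NA_real_, cc = NA_real_, n = 0))
    c(r = rValue(fo[sel], fc[sel], k),
      cc = .pearsonOrNA(io[sel], ic[sel]), n = sum(sel))
  }
  ns <- nShells(shells)
  e <- shells@edges
  rows <- lapply(seq_len(ns), function(i) {
    inS <- !is.na(idx) & idx == i
    w <- statsFor(inS & !free); f <- statsFor(inS & free)
    data.frame(dMax = e[i], dMin = e[i + 1], shell = as.character(i),
               nWork = as.integer(w["n"]), nFree = as.integer(f["n"]),
               rWork = w["r"], rFree = f["r"],
               rGap = f["r"] - w["r"],
               ccWork = w["cc"], ccFree = f["cc"],
               rWorkAboveFlag = !is.na(w["r"]) && w["r"] > rFlagLevel)
  })
  shellsDf <- do.call(rbind, rows)
  rownames(shellsDf) <- NULL
  w <- statsFor(!free); f <- statsFor(free)
  overall <- data.frame(dMax = e[1], dMin = e[length(e)], shell = "overall",
                        nWork = as.integer(w["n"]), nFree = as.integer(f["n"]),
                        rWork = w["r"], rFree = f["r"], rGap = f["r"] - w["r"],
                        ccWork = w["cc"], ccFree = f["cc"],
                        rWorkAboveFlag = !is.na(w["r"]) && w["r"] > rFlagLevel)
  rownames(overall) <- NULL
  new("AgreementReport", dCutoff = e[length(e)], scale = k,
      freeSet = as.integer(freeSet), overall = overall, shells = shellsDf)
}

#' Paired comparison of two refinement results at matched resolution
#'
#' The valid model-vs-model comparison of the paired-refinement protocol:
#' both models' structure factors are truncated to `d >= dCompare` (the
#' lower-resolution cutoff of the pair) and R values are computed against
#' the same data, each model with its own work-set scale. Differences are
#' reported as higher-resolution model minus lower-resolution model, so a
#' negative delta-Rfree means the added shell improved the model.
#'
#' @param resLow [RefinementResult-class] refined at the lower resolution
#'   (larger d).
#' @param resHigh [RefinementResult-class] refined at the higher
#'   resolution.
#' @param merged A [MergedSet-class] covering `d >= dCompare`.
#' @param dCompare Comparison cutoff; must equal the lower-resolution
#'   cutoff of the pair.
#' @param freeSet Free-flag value of the test set (default 0).
#' @return Named numeric: dRwork, dRfree.
#' @export
pairedR <- function(resLow, resHigh, merged, dCompare, freeSet = 0L) {
  data <- selectResolution(merged, dCompare)
  fo <- obsAmplitudes(data)
  free <- data@flag == freeSet
  oneModel <- function(res) {
    if (res@calc@dMin > dCompare + 1e-9)
      stop(sprintf("structure factors of the model refined at %.3f A do not reach %.3f A",
                   res@cutoff, dCompare))
    fcIdx <- match(friedelKey(data@hkl), friedelKey(res@calc@hkl))
    if (anyNA(fcIdx)) stop("calculated structure factors do not cover the comparison data")
    fc <- Mod(res@calc@fc)[fcIdx]
    k <- lsScale(fo[!free], fc[!free])
    c(work = rValue(fo[!free], fc[!free], k),
      free = if (any(free)) rValue(fo[free], fc[free], k) else NA_real_)
  }
  lo <- oneModel(resLow); hi <- oneModel(resHigh)
  c(dRwork = unname(hi["work"] - lo["work"]),
    dRfree = unname(hi["free"] - lo["free"]))
}
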