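## The paired-refinement ladder: stepwise refinement at increasing
## resolution with matched-resolution comparisons. The ladder reports; it
## never truncates the data or makes the cutoff decision.

#' Interpretation annotation for one ladder step
#'
#' Encodes the standard reading of a paired comparison as a label, not a
#' decision: a decrease in Rfree marks a shell beneficial to model
#' quality; a constant Rfree with a simultaneous increase in Rwork is
#' usually acceptable as well (it indicates less overfitting); an increase
#' in Rfree marks no improvement.
#'
#' @param dRwork,dRfree Paired R differences (higher- minus
#'   lower-resolution model, both at the lower cutoff).
#' @param tol Half-width of the "constant" band (default 5e-4).
#' @return Character annotation.
#' @export
annotateStep <- function(dRwork, dRfree, tol = 5e-4) {
  if (is.na(dRfree)) return("no free reflections: Rfree comparison unavailable")
  if (dRfree < -tol) return("Rfree decreased: shell beneficial to model quality")
  if (abs(dRfree) <= tol && !is.na(dRwork) && dRwork > tol)
    return("Rfree constant with Rwork increase: usually acceptable (less overfitting)")
  if (dRfree > tol) return("Rfree increased: no improvement from this shell")
  "no significant change"
}

## Overall agreement of a refinement result against the data truncated at
## dCut, as a one-row data.frame (used for the Rgap-at-A curve).
.overallAgreement <- function(res, merged, dCut, freeSet) {
  data <- selectResolution(merged, dCut)
  dmax <- max(dSpacing(data@cell, data@hkl))
  sh <- new("ShellScheme", edges = c(dmax + 1, dCut))
  agreementReport(data, res@calc, sh, freeSet = freeSet)@overall
}

#' Run the paired-refinement ladder
#'
#' Starting from a model refined at resolution `startRes` (A), refines
#' stepwise at each cutoff in `cutoffs` (descending d below A). For each
#' consecutive pair (X, Y) the newly refined model is compared with the
#' previous one, both against the data at X ([pairedR()]); the Y-model's
#' overall agreement at A supplies the Rgap curve; per-shell CCwork/CCfree
#' at Y (and CC* per shell when unmerged data are supplied) complete the
#' record. Steps whose shell contains no reflections are skipped with a
#' warning. By default each step starts from the previous step's refined
#' model (`restart = "cumulative"`); `restart = "fresh"` restarts every
#' cutoff from the input model as a sensitivity check.
#'
#' @param model An [AtomicModel-class] previously refined at `startRes`,
#'   or a [RefinementResult-class] at `startRes`.
#' @param merged A [MergedSet-class] covering the full cutoff range.
#' @param startRes Starting resolution A (Angstrom).
#' @param cutoffs Strictly decreasing cutoffs, all below `startRes`.
#' @param unmerged Optional [UnmergedSet-class] enabling the merging table
#'   and per-shell CC*.
#' @param backend Refinement backend ("toy" or "external").
#' @param freeSet Free-flag value of the test set (default 0).
#' @param nCycles Refinement cycles per step (default 20).
#' @param restart "cumulative" or "fresh".
#' @param seed Seed for the CC1/2 half splits of the merging table.
#' @param ... Passed to the backend.
#' @return A [LadderResult-class].
#' @export
runLadder <- function(model, merged, startRes, cutoffs, unmerged = NULL,
                      backend = "toy", freeSet = 0L, nCycles = 20L,
                      restart = c("cumulative", "fresh"), seed = 1L, ...) {
  restart <- match.arg(restart)
  if (any(cutoffs >= startRes))
    stop("every ladder cutoff must lie strictly below the starting resolution ",
         startRes, " (zero-length steps are not allowed)")
  if (any(diff(cutoffs) >= 0)) stop("cutoffs must be strictly decreasing in d")

  if (is(model, "RefinementResult")) {
    baseRes <- model
    baseModel <- model@model
  } else {
    baseRes <- refineModel(model, merged, startRes, nCycles = 0L,
                           freeSet = freeSet, backend = "toy")
    baseModel <- model
  }

  dAll <- dSpacing(merged@cell, merged@hkl)
  dmaxData <- max(dAll)
  fullEdges <- c(dmaxData + 1, startRes, cutoffs)
  mergingTab <- NULL
  ccStarByShell <- NULL
  if (!is.null(unmerged)) {
    umTrim <- selectResolution(unmerged, min(cutoffs))
    mergingTab <- mergingTable(umTrim, new("ShellScheme", edges = fullEdges),
                               seed = seed)
    ccStarByShell <- mergingTab$ccStar[mergingTab$shell != "overall"]
  }

  prevRes <- baseRes
  prevCut <- startRes
  models <- list(baseRes)
  stepRows <- list()
  shellRows <- list()
  for (i in seq_along(cutoffs)) {
    y <- cutoffs[i]
    nNew <- sum(dAll < prevCut & dAll >= y)
    if (nNew == 0) {
      warning(sprintf("shell %.3f-%.3f A contains no reflections; step skipped",
                      prevCut, y))
      next
    }
    res <- refineModel(if (restart == "cumulative") prevRes@model else baseModel,
                       merged, y, nCycles = nCycles, freeSet = freeSet,
                       backend = backend, ...)
    dR <- pairedR(prevRes, res, merged, dCompare = prevCut, freeSet = freeSet)
    agA <- .overallAgreement(res, merged, startRes, freeSet)
    shY <- new("ShellScheme", edges = fullEdges[fullEdges >= y - 1e-9])
    repY <- agreementReport(selectResolution(merged, y), res@calc, shY,
                            freeSet = freeSet)
    shDf <- repY@shells
    shDf$ccStar <- if (!is.null(ccStarByShell))
      ccStarByShell[seq_len(nrow(shDf))] else NA_real_
    shDf <- cbind(step = i, from = prevCut, to = y, shDf)
    stepRows[[length(stepRows) + 1L]] <- data.frame(
      step = i, from = prevCut, to = y,
      dRwork = dR["dRwork"], dRfree = dR["dRfree"],
      rWorkA = agA$rWork, rFreeA = agA$rFree, rGapA = agA$rGap,
      scale = res@scale, cycles = res@cycles,
      annotation = annotateStep(dR["dRwork"], dR["dRfree"]))
    shellRows[[length(shellRows) + 1L]] <- shDf
    models[[length(models) + 1L]] <- res
    prevRes <- res
    prevCut <- y
  }
  steps <- if (length(stepRows)) do.call(rbind, stepRows) else
    data.frame(step = integer(0), from = numeric(0), to = numeric(0),
               dRwork = numeric(0), dRfree = numeric(0), rWorkA = numeric(0),
               rFreeA = numeric(0), rGapA = numeric(0), scale = numeric(0),
               cycles = integer(0), annotation = character(0))
  rownames(steps) <- NULL
  shellStats <- if (length(shellRows)) do.call(rbind, shellRows) else data.frame()
  rownames(shellStats) <- NULL
  new("LadderResult", startRes = startRes, steps = steps,
      shellStats = shellStats, models = models,
      freeSet = as.integer(freeSet), merging = mergingTab)
}
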