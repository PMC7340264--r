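## Complete (k-fold) cross-validation over the CCP4-style free-flag sets.

#' Aggregate per-free-set step differences
#'
#' Pure aggregation used by the complete cross-validation protocol: per
#' step (column), the mean, sample standard deviation, standard error of
#' the mean (`SEM = SD/sqrt(k)`, k = number of free sets), and the counts
#' of rises (> 0) and falls (< 0) across free sets.
#'
#' @param values Numeric matrix, rows = free sets, columns = steps.
#' @return data.frame with columns step, mean, sd, sem, rises, falls.
#' @export
cvAggregate <- function(values) {
  values <- as.matrix(values)
  k <- nrow(values)
  data.frame(step = seq_len(ncol(values)),
             mean = colMeans(values),
             sd = apply(values, 2, stats::sd),
             sem = apply(values, 2, stats::sd) / sqrt(k),
             rises = colSums(values > 0),
             falls = colSums(values < 0))
}

#' Complete cross-validation paired refinement
#'
#' Runs the full ladder once per free-flag set q = 0..k-1. To remove the
#' bias of previous refinement against a particular free set, the input
#' model is modified before each run — coordinate perturbation and ADP
#' reset/shift per `modifications` — with a per-set seed derived
#' deterministically from `seed`, then re-refined at the starting
#' resolution before its ladder. Per-step mean, sample SD and SEM of
#' delta-Rwork, delta-Rfree and Rgap(A) are aggregated across sets, along
#' with rise/fall counts of delta-Rfree.
#'
#' @param model [AtomicModel-class] refined at `startRes`.
#' @param merged [MergedSet-class] with at least two free-flag sets.
#' @param startRes Starting resolution A.
#' @param cutoffs Strictly decreasing ladder cutoffs below A.
#' @param modifications List with optional elements `perturb` (mean shift,
#'   Angstrom), `resetAdp` ("mean" or a numeric B value), `shiftAdp`
#'   (additive B shift).
#' @param backend,nCycles,restart,seed,... As in [runLadder()]; `nCycles`
#'   is also used for the per-set re-refinement at A.
#' @return A [CrossValResult-class].
#' @export
runCompleteCV <- function(model, merged, startRes, cutoffs,
                          modifications = list(perturb = 0.25, resetAdp = "mean"),
                          backend = "toy", nCycles = 20L,
                          restart = "cumulative", seed = 1L, ...) {
  k <- merged@flagCount
  if (k < 2L)
    stop("complete cross-validation needs CCP4-style multi-set free flags ",
         "(flagCount >= 2); this data set has k = ", k)
  results <- vector("list", k)
  for (q in seq_len(k) - 1L) {
    sq <- childSeed(seed, q + 1L)
    m <- model
    if (!is.null(modifications$perturb) && modifications$perturb > 0)
      m <- perturbCoordinates(m, modifications$perturb, seed = sq)
    if (!is.null(modifications$resetAdp)) {
      m <- if (identical(modifications$resetAdp, "mean")) resetADP(m, "mean")
      else resetADP(m, "value", value = modifications$resetAdp)
    }
    if (!is.null(modifications$shiftAdp))
      m <- shiftADP(m, modifications$shiftAdp)
    resA <- refineModel(m, merged, startRes, nCycles = nCycles, freeSet = q,
                        backend = backend, ...)
    results[[q + 1L]] <- runLadder(resA, merged, startRes, cutoffs,
                                   backend = backend, freeSet = q,
                                   nCycles = nCycles, restart = restart,
                                   seed = sq, ...)
  }
  nSteps <- nrow(results[[1]]@steps)
  pull <- function(col) t(vapply(results, function(r) r@steps[[col]], numeric(nSteps)))
  aggW <- cvAggregate(pull("dRwork"))
  aggF <- cvAggregate(pull("dRfree"))
  aggG <- cvAggregate(pull("rGapA"))
  summary <- data.frame(
    step = aggF$step,
    from = results[[1]]@steps$from, to = results[[1]]@steps$to,
    meanDRwork = aggW$mean, sdDRwork = aggW$sd, semDRwork = aggW$sem,
    meanDRfree = aggF$mean, sdDRfree = aggF$sd, semDRfree = aggF$sem,
    meanRgapA = aggG$mean, sdRgapA = aggG$sd, semRgapA = aggG$sem,
    rises = aggF$rises, falls = aggF$falls)
  new("CrossValResult", results = results, summary = summary, k = as.integer(k))
}
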