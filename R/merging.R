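## Merging statistics on unmerged intensities: multiplicity, completeness,
## mean I/sigma, Rmerge/Rmeas/Rpim, CC1/2 (+ significance), CC*.

#' Merge multiply-observed intensities
#'
#' Groups observations by Friedel-canonical index and returns the
#' unweighted mean intensity, the propagated sigma of the mean
#' (`sqrt(sum(sigma_i^2))/n`) and the multiplicity of each unique
#' reflection.
#'
#' @param x An [UnmergedSet-class].
#' @return data.frame with columns h, k, l, d, i, sigma, n.
#' @export
mergeIntensities <- function(x) {
  if (nrow(x@hkl) == 0) stop("cannot merge an empty set")
  key <- friedelKey(x@hkl)
  ord <- order(match(key, unique(key)))
  grp <- factor(key, levels = unique(key))
  n <- as.integer(table(grp))
  imean <- as.numeric(tapply(x@intensity, grp, mean))
  smerg <- sqrt(as.numeric(tapply(x@sigma^2, grp, sum))) / n
  hklu <- friedelReduce(x@hkl)[!duplicated(key), , drop = FALSE]
  data.frame(h = hklu[, 1], k = hklu[, 2], l = hklu[, 3],
             d = dSpacing(x@cell, hklu), i = imean, sigma = smerg, n = n)
}

## Per-unique absolute deviation sums for the R metrics; returns one row per
## unique with n >= 2 (singly observed reflections contribute to neither
## numerator nor denominator).
.rParts <- function(x) {
  key <- friedelKey(x@hkl)
  grp <- factor(key, levels = unique(key))
  n <- as.integer(table(grp))
  imean <- as.numeric(tapply(x@intensity, grp, mean))
  dev <- as.numeric(tapply(x@intensity, grp, function(v) sum(abs(v - mean(v)))))
  isum <- as.numeric(tapply(x@intensity, grp, sum))
  hklu <- friedelReduce(x@hkl)[!duplicated(key), , drop = FALSE]
  data.frame(d = dSpacing(x@cell, hklu), n = n, dev = dev, isum = isum)
}

.rFromParts <- function(p) {
  p <- p[p$n >= 2L, , drop = FALSE]
  if (nrow(p) == 0 || sum(p$isum) == 0)
    return(c(rMerge = NA_real_, rMeas = NA_real_, rPim = NA_real_))
  den <- sum(p$isum)
  c(rMerge = sum(p$dev) / den,
    rMeas  = sum(sqrt(p$n / (p$n - 1)) * p$dev) / den,
    rPim   = sum(sqrt(1 / (p$n - 1)) * p$dev) / den)
}

#' Rmerge, Rmeas and Rpim
#'
#' Internal-agreement residuals of multiply-observed intensities:
#' `Rmerge = sum |I_i - <I>| / sum I_i`; Rmeas multiplies each unique's
#' deviation sum by `sqrt(n/(n-1))` (multiplicity-corrected) and Rpim by
#' `sqrt(1/(n-1))` (precision of the merged mean). Uniques observed once
#' are excluded from both numerator and denominator. The overall row pools
#' all shells.
#'
#' @param x An [UnmergedSet-class].
#' @param shells A [ShellScheme-class].
#' @return data.frame: one row per shell plus an overall row, with columns
#'   dMax, dMin, rMerge, rMeas, rPim (NA where no unique has n >= 2).
#' @export
rMetrics <- function(x, shells) {
  p <- .rParts(x)
  idx <- shellAssign(shells, p$d)
  e <- shells@edges
  rows <- lapply(seq_len(nShells(shells)), function(i)
    .rFromParts(p[!is.na(idx) & idx == i, , drop = FALSE]))
  ov <- .rFromParts(p[!is.na(idx), , drop = FALSE])
  out <- as.data.frame(do.call(rbind, c(rows, list(ov))))
  data.frame(dMax = c(e[-length(e)], e[1]), dMin = c(e[-1], e[length(e)]),
             shell = c(as.character(seq_len(nShells(shells))), "overall"), out)
}

## Split observations of each contributing unique into two halves and
## return the two half-mean vectors (per shell grouping done by caller).
## n = 2 splits deterministically (first observation to half A); larger
## groups are permuted with the seeded RNG; for odd n the surplus
## observation alternates between halves across uniques.
.halfMeans <- function(x, seed) {
  key <- friedelKey(x@hkl)
  grp <- factor(key, levels = unique(key))
  n <- as.integer(table(grp))
  keep <- levels(grp)[n >= 2L]
  if (!length(keep)) return(NULL)
  splitIdx <- split(seq_along(key), grp)
  withSeed(seed, {
    surplusToA <- TRUE
    ha <- hb <- numeric(length(keep))
    for (j in seq_along(keep)) {
      ii <- splitIdx[[keep[j]]]
      m <- length(ii)
      if (m > 2L) ii <- ii[sample.int(m)]
      na <- m %/% 2L
      if (m %% 2L == 1L) {
        if (surplusToA) na <- na + 1L
        surplusToA <- !surplusToA
      }
      ha[j] <- mean(x@intensity[ii[seq_len(na)]])
      hb[j] <- mean(x@intensity[ii[(na + 1L):m]])
    }
    ## d per kept unique, taken from its first stored observation
    dKeep <- dSpacing(x@cell, friedelReduce(x@hkl)[match(keep, key), , drop = FALSE])
    data.frame(d = dKeep, ha = ha, hb = hb)
  })
}

.ccFromHalves <- function(h) {
  if (is.null(h) || nrow(h) < 3L) return(NA_real_)
  if (stats::sd(h$ha) == 0 || stats::sd(h$hb) == 0) return(NA_real_)
  stats::cor(h$ha, h$hb)
}

#' Half-set correlation CC1/2
#'
#' For each unique reflection observed at least twice, the observations are
#' split into two halves (seeded random split; deterministic for n = 2) and
#' the Pearson correlation between the two half-mean vectors is computed
#' across the uniques of each shell. Shells with fewer than three
#' contributing uniques, or zero variance in either half, yield NA. The
#' overall value pools all shells.
#'
#' @param x An [UnmergedSet-class].
#' @param shells A [ShellScheme-class].
#' @param seed Integer seed for the random splits.
#' @return data.frame with one row per shell plus an overall row: dMax,
#'   dMin, ccHalf, nPairs (contributing uniques).
#' @export
ccHalf <- function(x, shells, seed = 1L) {
  h <- .halfMeans(x, seed)
  e <- shells@edges
  idx <- if (is.null(h)) integer(0) else shellAssign(shells, h$d)
  per <- lapply(seq_len(nShells(shells)), function(i) {
    hi <- h[!is.na(idx) & idx == i, , drop = FALSE]
    c(cc = .ccFromHalves(hi), n = if (is.null(h)) 0L else nrow(hi))
  })
  hAll <- if (is.null(h)) NULL else h[!is.na(idx), , drop = FALSE]
  ov <- c(cc = .ccFromHalves(hAll), n = if (is.null(hAll)) 0L else nrow(hAll))
  m <- do.call(rbind, c(per, list(ov)))
  data.frame(dMax = c(e[-length(e)], e[1]), dMin = c(e[-1], e[length(e)]),
             shell = c(as.character(seq_len(nShells(shells))), "overall"),
             ccHalf = m[, "cc"], nPairs = as.integer(m[, "n"]))
}

#' Significance of a correlation coefficient
#'
#' One-sided Student test of CC > 0: `t = cc * sqrt((n-2)/(1-cc^2))` with
#' `n - 2` degrees of freedom; significant iff p < alpha (default the
#' 1:1000 level used for CC1/2).
#'
#' @param cc Correlation coefficient(s), |cc| < 1.
#' @param nPairs Number of pairs entering each correlation.
#' @param alpha Significance level (default 0.001).
#' @return Logical vector (NA where nPairs < 3 or cc is NA).
#' @export
ccSignificance <- function(cc, nPairs, alpha = 0.001) {
  out <- rep(NA, length(cc))
  ok <- !is.na(cc) & nPairs >= 3L & abs(cc) < 1
  t <- cc[ok] * sqrt((nPairs[ok] - 2) / (1 - cc[ok]^2))
  out[ok] <- stats::pt(t, df = nPairs[ok] - 2, lower.tail = FALSE) < alpha
  out
}

#' CC* from CC1/2
#'
#' `CC* = sqrt(2 CC1/2 / (1 + CC1/2))`: the estimated correlation of the
#' merged data with the (unknown) true signal, the model-independent
#' ceiling against which CCwork/CCfree are compared.
#'
#' @param ccHalf Numeric CC1/2 value(s); must exceed -1.
#' @return CC* values; NA for negative CC1/2 (undefined transform).
#' @examples
#' ccStar(0.5)  # 0.8165
#' @export
ccStar <- function(ccHalf) {
  if (any(ccHalf <= -1, na.rm = TRUE)) stop("CC1/2 must exceed -1")
  out <- rep(NA_real_, length(ccHalf))
  names(out) <- names(ccHalf)
  pos <- !is.na(ccHalf) & ccHalf >= 0
  out[pos] <- sqrt(2 * ccHalf[pos] / (1 + ccHalf[pos]))
  out
}

#' Shell completeness
#'
#' Percentage of the Friedel-unique index sphere observed in each shell.
#' The denominator enumerates all Friedel-canonical indices of the cell
#' with d inside the shell (P1; no further symmetry), down to the scheme's
#' final edge.
#'
#' @param x A [MergedSet-class] or [UnmergedSet-class].
#' @param shells A [ShellScheme-class].
#' @return data.frame: per shell plus overall, with nUniqueObs, nPossible,
#'   completeness (%).
#' @export
shellCompleteness <- function(x, shells) {
  e <- shells@edges
  all <- enumerateUnique(x@cell, e[length(e)], e[1])
  dAll <- dSpacing(x@cell, all)
  iAll <- shellAssign(shells, dAll)
  key <- unique(friedelKey(x@hkl))
  hklObs <- friedelReduce(x@hkl)[!duplicated(friedelKey(x@hkl)), , drop = FALSE]
  dObs <- dSpacing(x@cell, hklObs)
  iObs <- shellAssign(shells, dObs)
  ns <- nShells(shells)
  poss <- tabulate(iAll, nbins = ns)
  obs <- tabulate(iObs[!is.na(iObs)], nbins = ns)
  comp <- ifelse(poss > 0, 100 * obs / poss, 0)
  data.frame(dMax = c(e[-length(e)], e[1]), dMin = c(e[-1], e[length(e)]),
             shell = c(as.character(seq_len(ns)), "overall"),
             nUniqueObs = c(obs, sum(obs)), nPossible = c(poss, sum(poss)),
             completeness = c(comp, ifelse(sum(poss) > 0, 100 * sum(obs) / sum(poss), 0)))
}

#' Full merging-statistics table
#'
#' One row per resolution shell plus a pooled overall row, carrying
#' observation and unique counts, multiplicity, completeness, mean
#' I/sigma of the merged intensities, Rmerge/Rmeas/Rpim, CC1/2 with its
#' 1:1000-level significance and CC*. Undefined entries are carried as NA,
#' never 0. Deterministic for a fixed seed.
#'
#' @param x An [UnmergedSet-class].
#' @param shells A [ShellScheme-class].
#' @param seed Seed for the CC1/2 half splits.
#' @return data.frame of merging statistics.
#' @export
mergingTable <- function(x, shells, seed = 1L) {
  mrg <- mergeIntensities(x)
  idxU <- shellAssign(shells, mrg$d)
  dObs <- dSpacing(x@cell, x@hkl)
  idxO <- shellAssign(shells, dObs)
  ns <- nShells(shells)
  nUniq <- tabulate(idxU[!is.na(idxU)], nbins = ns)
  nObs <- tabulate(idxO[!is.na(idxO)], nbins = ns)
  isig <- vapply(seq_len(ns), function(i) {
    s <- mrg[!is.na(idxU) & idxU == i, , drop = FALSE]
    if (nrow(s) == 0) NA_real_ else mean(s$i / s$sigma)
  }, numeric(1))
  comp <- shellCompleteness(x, shells)
  rm <- rMetrics(x, shells)
  cc <- ccHalf(x, shells, seed)
  nU <- c(nUniq, sum(nUniq)); nO <- c(nObs, sum(nObs))
  sAll <- !is.na(idxU)
  isigAll <- if (any(sAll)) mean(mrg$i[sAll] / mrg$sigma[sAll]) else NA_real_
  out <- data.frame(
    dMax = comp$dMax, dMin = comp$dMin, shell = comp$shell,
    nObservations = nO, nUnique = nU,
    multiplicity = ifelse(nU > 0, nO / nU, NA_real_),
    completeness = comp$completeness,
    meanIOverSigma = c(isig, isigAll),
    rMerge = rm$rMerge, rMeas = rm$rMeas, rPim = rm$rPim,
    ccHalf = cc$ccHalf,
    ccHalfSignificant = ccSignificance(cc$ccHalf, cc$nPairs),
    ccStar = ccStar(pmax(cc$ccHalf, -0.999999, na.rm = FALSE)))
  out
}
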