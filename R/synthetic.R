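## Synthetic ground-truth models and diffraction data with a planted
## information limit: the test substrate for the whole protocol.

#' Generator configuration
#'
#' Collects the simulation knobs with the package's standard study
#' conditions as defaults: a P1 orthorhombic-shaped 30 x 35 x 40 Angstrom
#' cell, 40 carbon-like atoms with B uniform in [10, 30] square Angstrom,
#' data generated to 1.2 Angstrom at multiplicity 4, relative noise
#' a = 0.05 and additive per-shell noise b = 0.10, an information limit
#' `dInfo` of 1.5 Angstrom with a 0.05 Angstrom transition, and 20
#' CCP4-style free-flag sets (a 5% free fraction per set).
#'
#' Beyond `dInfo`, observed intensities blend smoothly into pure
#' shell-scaled noise: the planted limit recovery experiments test whether
#' the ladder finds it.
#'
#' @param cell [UnitCell-class] (default 30 x 35 x 40, P1).
#' @param nAtoms Number of atoms (default 40).
#' @param bRange B-factor range in square Angstrom (default c(10, 30)).
#' @param dMin Generation resolution limit (default 1.2).
#' @param multiplicity Observations per unique reflection (default 4).
#' @param noiseRel Relative noise fraction a (default 0.05).
#' @param noiseShell Additive per-shell noise fraction b (default 0.10).
#' @param dInfo Planted information limit (default 1.5; must be >= dMin).
#' @param transition Width of the signal-to-noise transition in d
#'   (default 0.05).
#' @param freeFraction Free fraction per set f (default 0.05).
#' @param nFlagSets Number of free-flag sets k (default 20).
#' @param seed Master seed.
#' @return A validated list of class "GeneratorConfig".
#' @export
generatorConfig <- function(cell = unitCellNew(30, 35, 40), nAtoms = 40L,
                            bRange = c(10, 30), dMin = 1.2, multiplicity = 4L,
                            noiseRel = 0.05, noiseShell = 0.10, dInfo = 1.5,
                            transition = 0.05, freeFraction = 0.05,
                            nFlagSets = 20L, seed = 1L) {
  if (nAtoms < 1) stop("nAtoms must be >= 1")
  if (dInfo < dMin) stop("dInfo must be >= dMin")
  if (!(freeFraction > 0 && freeFraction < 1)) stop("freeFraction must lie in (0, 1)")
  if (nFlagSets < 1) stop("nFlagSets must be >= 1")
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  structure(list(cell = cell, nAtoms = as.integer(nAtoms), bRange = bRange,
                 dMin = dMin, multiplicity = as.integer(multiplicity),
                 noiseRel = noiseRel, noiseShell = noiseShell, dInfo = dInfo,
                 transition = transition, freeFraction = freeFraction,
                 nFlagSets = as.integer(nFlagSets), seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Generate a ground-truth model
#'
#' `nAtoms` carbon-like point atoms (Z = 6) uniform in the cell, B uniform
#' in `bRange`, occupancy 1; deterministic for the config's seed.
#'
#' @param config A [generatorConfig()] list.
#' @return An [AtomicModel-class].
#' @export
generateTruth <- function(config) {
  withSeed(config$seed, {
    n <- config$nAtoms
    atomicModel(config$cell,
                data.frame(element = rep("C", n),
                           x = stats::runif(n), y = stats::runif(n),
                           z = stats::runif(n), occ = rep(1, n),
                           b = stats::runif(n, config$bRange[1], config$bRange[2])),
                label = "truth")
  })
}

## Signal weight w(d): 1 for d >= dInfo, cosine ramp to 0 across the
## transition, 0 beyond it.
.signalWeight <- function(d, dInfo, transition) {
  if (transition <= 0) return(as.numeric(d >= dInfo))
  w <- (d - (dInfo - transition)) / transition
  pmin(1, pmax(0, 0.5 - 0.5 * cos(pi * pmin(1, pmax(0, w)))))
}

#' Generate merged and unmerged data from a truth model
#'
#' Enumerates the Friedel-unique sphere to `dMin`, computes true
#' intensities `|Fc|^2`, and produces `multiplicity` observations per
#' unique: `I_obs = w I_true + (1 - w) J + eps`, where `w(d)` is 1 down to
#' the planted limit `dInfo` and decays smoothly to 0 across the
#' transition; `J` is pure noise drawn per observation from an exponential
#' with the shell's mean true intensity; and `eps` is Gaussian with
#' `sigma = a |signal| + b <I>_shell`. Sigmas are recorded accordingly
#' (with a tiny floor so the noise-free limit stays valid). The merged set
#' carries amplitudes `|Fo| = sqrt(max(I, 0))` and free flags uniform over
#' `0..k-1` per unique reflection. Deterministic for the config's seed.
#'
#' @param truth An [AtomicModel-class].
#' @param config A [generatorConfig()] list.
#' @return List with elements `merged` ([MergedSet-class]) and `unmerged`
#'   ([UnmergedSet-class]).
#' @export
generateData <- function(truth, config) {
  hkl <- enumerateUnique(truth@cell, config$dMin)
  d <- dSpacing(truth@cell, hkl)
  itrue <- Mod(calcStructureFactors(truth, hkl, dMin = config$dMin)@fc)^2
  ## shell-mean true intensity on a fixed 0.1 A grid (resolution-dependent
  ## noise scale)
  bin <- floor(pmin(d, 10) / 0.1)
  meanI <- tapply(itrue, bin, mean)[as.character(bin)]
  w <- .signalWeight(d, config$dInfo, config$transition)
  m <- config$multiplicity
  nU <- nrow(hkl)
  withSeed(childSeed(config$seed, 2L), {
    idx <- rep(seq_len(nU), each = m)
    signal <- w[idx] * itrue[idx]
    jn <- (1 - w[idx]) * stats::rexp(nU * m, rate = 1 / meanI[idx])
    sigma <- config$noiseRel * abs(signal + (1 - w[idx]) * meanI[idx]) +
      config$noiseShell * meanI[idx]
    iobs <- signal + jn + stats::rnorm(nU * m, sd = sigma)
    sigmaRec <- pmax(sqrt(sigma^2 + ((1 - w[idx]) * meanI[idx])^2), 1e-6)
    unm <- unmergedSet(truth@cell, hkl[idx, , drop = FALSE], iobs, sigmaRec,
                       label = "synthetic")
    mrg <- mergeIntensities(unm)
    flags <- sample.int(config$nFlagSets, nU, replace = TRUE) - 1L
    fo <- sqrt(pmax(mrg$i, 0))
    sigF <- ifelse(fo > 0, mrg$sigma / (2 * fo), sqrt(pmax(mrg$sigma, 1e-6)))
    merged <- mergedSet(truth@cell, as.matrix(mrg[, c("h", "k", "l")]),
                        fo, pmax(sigF, 1e-6), flags, kind = "F",
                        nFlagSets = config$nFlagSets)
    list(merged = merged, unmerged = unm)
  })
}

#' Degrade a truth model into a refinement starting model
#'
#' Applies the standard model-preparation recipe: coordinate perturbation
#' by a mean shift of `perturb` Angstrom, then an ADP reset ("mean" or an
#' explicit value). This emulates a model refined at lower resolution
#' whose memory of the data must be erased before cross-validation.
#'
#' @param truth An [AtomicModel-class].
#' @param config A [generatorConfig()] list.
#' @param perturb Mean coordinate shift (default 0.25 Angstrom).
#' @param resetAdp "mean", a numeric B value, or NULL to leave ADPs
#'   untouched.
#' @return An [AtomicModel-class].
#' @export
degradeModel <- function(truth, config, perturb = 0.25, resetAdp = "mean") {
  m <- truth
  if (perturb > 0)
    m <- perturbCoordinates(m, perturb, seed = childSeed(config$seed, 3L))
  if (!is.null(resetAdp)) {
    m <- if (identical(resetAdp, "mean")) resetADP(m, "mean")
    else resetADP(m, "value", value = resetAdp)
  }
  m@label <- "degraded"
  m
}
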