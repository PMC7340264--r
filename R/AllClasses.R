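## S4 class definitions for the reflection-data, model and result containers.

#' Crystallographic unit cell
#'
#' Cell edge lengths in Angstrom and angles in degrees. Validity requires
#' positive lengths, angles in (0, 180) and a positive-definite metric
#' tensor (i.e. a geometrically realisable cell).
#'
#' @slot a,b,c Cell edges (Angstrom).
#' @slot alpha,beta,gamma Cell angles (degrees).
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("UnitCell", function(object) {
  p <- c(object@a, object@b, object@c, object@alpha, object@beta, object@gamma)
  if (length(p) != 6L || any(!is.finite(p)))
    return("all six cell parameters must be finite scalars")
  if (any(p[1:3] <= 0)) return("cell lengths must be positive")
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) return("cell angles must lie in (0, 180)")
  ca <- cos(p[4] * pi / 180); cb <- cos(p[5] * pi / 180); cg <- cos(p[6] * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) return("cell angles do not define a positive-definite metric")
  TRUE
})

#' Resolution shell scheme
#'
#' Descending d-spacing edges defining contiguous resolution shells.
#' Shell i spans `[edges[i], edges[i+1])` in d; the final shell is closed
#' at the last edge so the scheme covers its full range inclusively.
#'
#' @slot edges Strictly decreasing d-spacing edges (Angstrom), length >= 2.
#' @export
setClass("ShellScheme", representation(edges = "numeric"))

setValidity("ShellScheme", function(object) {
  e <- object@edges
  if (length(e) < 2L) return("need at least two shell edges")
  if (any(!is.finite(e)) || any(e <= 0)) return("shell edges must be positive")
  if (any(diff(e) >= 0)) return("shell edges must be strictly decreasing in d")
  TRUE
})

#' Merged reflection data
#'
#' Unique (Friedel-reduced) reflections with an amplitude or intensity
#' column, standard uncertainties and a CCP4-style free-flag integer in
#' `0..flagCount-1`. `kind` declares whether `value` holds amplitudes
#' ("F") or intensities ("I").
#'
#' @slot cell A [UnitCell-class].
#' @slot hkl Integer matrix (n x 3) of Miller indices, Friedel-reduced.
#' @slot value Amplitudes |Fo| or intensities Io.
#' @slot sigma Standard uncertainties, all > 0.
#' @slot flag Integer free flags in `0..flagCount-1`.
#' @slot kind "F" or "I".
#' @slot flagCount Number of free-flag sets k (>= 1).
#' @export
setClass("MergedSet",
  representation(cell = "UnitCell", hkl = "matrix", value = "numeric",
                 sigma = "numeric", flag = "integer", kind = "character",
                 flagCount = "integer"))

setValidity("MergedSet", function(object) {
  n <- nrow(object@hkl)
  if (ncol(object@hkl) != 3L) return("hkl must have three columns")
  if (length(object@value) != n || length(object@sigma) != n ||
      length(object@flag) != n)
    return("value, sigma and flag must match the number of reflections")
  if (n > 0 && any(rowSums(object@hkl != 0) == 0)) return("(0,0,0) is not a valid index")
  if (any(object@sigma <= 0)) return("all sigmas must be positive")
  if (!object@kind %in% c("F", "I")) return("kind must be 'F' or 'I'")
  if (object@flagCount < 1L) return("flagCount must be >= 1")
  if (n > 0 && (any(object@flag < 0L) || any(object@flag >= object@flagCount)))
    return("free flags must lie in 0..flagCount-1")
  if (n > 0 && anyDuplicated(friedelKey(object@hkl)))
    return("duplicate Miller indices after Friedel reduction")
  TRUE
})

#' Unmerged intensity observations
#'
#' Multiply-observed intensities keyed by Miller index; the substrate of
#' the merging statistics. Friedel mates are reduced on demand, not at
#' storage time.
#'
#' @slot cell A [UnitCell-class].
#' @slot hkl Integer matrix (n x 3) of Miller indices (one row per observation).
#' @slot intensity Observed intensities (negative values permitted).
#' @slot sigma Standard uncertainties, all > 0.
#' @slot label Provenance label.
#' @export
setClass("UnmergedSet",
  representation(cell = "UnitCell", hkl = "matrix", intensity = "numeric",
                 sigma = "numeric", label = "character"))

setValidity("UnmergedSet", function(object) {
  n <- nrow(object@hkl)
  if (ncol(object@hkl) != 3L) return("hkl must have three columns")
  if (length(object@intensity) != n || length(object@sigma) != n)
    return("intensity and sigma must match the number of observations")
  if (n > 0 && any(rowSums(object@hkl != 0) == 0)) return("(0,0,0) is not a valid index")
  if (any(object@sigma <= 0)) return("all sigmas must be positive")
  TRUE
})

#' Atomic model with isotropic displacement parameters
#'
#' Atoms carry an element symbol, electron count, fractional coordinates,
#' occupancy and an isotropic B factor. Atom order is stable across I/O
#' round trips, which defines the identity pairing used by the RMSD
#' functions.
#'
#' @slot cell A [UnitCell-class].
#' @slot atoms data.frame with columns element, z, x, y, z (fractional),
#'   occ, b.
#' @slot label Model label.
#' @export
setClass("AtomicModel",
  representation(cell = "UnitCell", atoms = "data.frame", label = "character"))

setValidity("AtomicModel", function(object) {
  need <- c("element", "zeff", "x", "y", "z", "occ", "b")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  a <- object@atoms
  if (nrow(a) == 0) return("model has no atoms")
  if (any(a$b <= 0)) return("all B factors must be positive")
  if (any(a$occ < 0 | a$occ > 1)) return("occupancies must lie in [0, 1]")
  if (any(a$zeff <= 0)) return("electron counts must be positive")
  TRUE
})

#' Calculated structure factors
#'
#' Complex structure factors for a set of Friedel-unique indices, with the
#' resolution limit they extend to.
#'
#' @slot cell A [UnitCell-class].
#' @slot hkl Integer matrix of Friedel-unique indices.
#' @slot fc Complex structure factors.
#' @slot dMin High-resolution limit of the set (Angstrom).
#' @export
setClass("CalcSet",
  representation(cell = "UnitCell", hkl = "matrix", fc = "complex",
                 dMin = "numeric"))

setValidity("CalcSet", function(object) {
  if (nrow(object@hkl) != length(object@fc))
    return("fc must match the number of indices")
  TRUE
})

#' Result of one refinement run
#'
#' The refined model, calculated structure factors for every reflection
#' (work and free) to the refinement cutoff, the per-cycle working residual
#' trace (non-increasing), the fitted scale and the cutoff used.
#'
#' @slot model Refined [AtomicModel-class].
#' @slot calc [CalcSet-class] at the refinement cutoff.
#' @slot trace Per-cycle working residual (sum of squares), non-increasing.
#' @slot scale Fitted linear scale k on amplitudes.
#' @slot cutoff Refinement resolution cutoff (Angstrom).
#' @slot cycles Cycles actually run.
#' @slot note Backend diagnostics (e.g. fallback events).
#' @export
setClass("RefinementResult",
  representation(model = "AtomicModel", calc = "CalcSet", trace = "numeric",
                 scale = "numeric", cutoff = "numeric", cycles = "integer",
                 note = "character"))

setValidity("RefinementResult", function(object) {
  tr <- object@trace
  if (length(tr) > 1 && any(diff(tr) > 1e-9 * (1 + abs(tr[-length(tr)]))))
    return("working residual trace must be non-increasing")
  TRUE
})

#' Model-vs-data agreement report
#'
#' Overall and per-shell Rwork/Rfree/Rgap and CCwork/CCfree at a stated
#' cutoff, with the work-set scale and per-shell reflection counts.
#' `Rgap = Rfree - Rwork` holds exactly on every row where both are defined.
#'
#' @slot dCutoff Resolution cutoff the report was computed at.
#' @slot scale Work-set least-squares scale k.
#' @slot freeSet Free-flag value treated as the test set.
#' @slot overall One-row data.frame of overall statistics.
#' @slot shells Per-shell data.frame of statistics and counts.
#' @export
setClass("AgreementReport",
  representation(dCutoff = "numeric", scale = "numeric", freeSet = "integer",
                 overall = "data.frame", shells = "data.frame"))

#' Paired-refinement ladder result
#'
#' Ordered per-step records of the paired comparisons (delta-R at the lower
#' cutoff of each pair), the agreement of each step's model at the starting
#' resolution (the Rgap curve), and per-shell CC statistics, plus the
#' refined models themselves. The tool reports; it never truncates the data
#' or decides the cutoff.
#'
#' @slot startRes Starting resolution A (Angstrom).
#' @slot steps Per-step data.frame (from, to, dRwork, dRfree, rWorkA,
#'   rFreeA, rGapA, annotation, ...).
#' @slot shellStats Per-step per-shell data.frame of CC statistics.
#' @slot models List of per-step [RefinementResult-class] objects (first
#'   element is the starting-resolution refinement).
#' @slot freeSet Free-flag set used as the test set.
#' @slot merging Merging-statistics table (data.frame) or NULL.
#' @export
setClass("LadderResult",
  representation(startRes = "numeric", steps = "data.frame",
                 shellStats = "data.frame", models = "list",
                 freeSet = "integer", merging = "ANY"))

setValidity("LadderResult", function(object) {
  s <- object@steps
  if (nrow(s) > 1 && any(abs(s$from[-1] - s$to[-nrow(s)]) > 1e-9))
    return("ladder steps must be contiguous: each step's start equals the previous step's end")
  TRUE
})

#' Complete cross-validation result
#'
#' Per-free-set ladder results plus per-step aggregation (mean, sample SD,
#' SEM = SD/sqrt(k)) of the monitored differences, and counts of rises and
#' falls of delta-Rfree across free sets.
#'
#' @slot results List of [LadderResult-class], one per free set q = 0..k-1.
#' @slot summary Per-step aggregate data.frame.
#' @slot k Number of free-flag sets.
#' @export
setClass("CrossValResult",
  representation(results = "list", summary = "data.frame", k = "integer"))
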