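## Generics and simple accessors / show methods.

#' Unit cell of an object
#' @param x An object carrying a [UnitCell-class].
#' @return The [UnitCell-class].
#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))

#' @rdname unitCell
setMethod("unitCell", "MergedSet", function(x) x@cell)
#' @rdname unitCell
setMethod("unitCell", "UnmergedSet", function(x) x@cell)
#' @rdname unitCell
setMethod("unitCell", "AtomicModel", function(x) x@cell)
#' @rdname unitCell
setMethod("unitCell", "CalcSet", function(x) x@cell)

#' Number of reflections or observations
#' @param x A [MergedSet-class], [UnmergedSet-class] or [CalcSet-class].
#' @return Integer count.
#' @export
setGeneric("nReflections", function(x) standardGeneric("nReflections"))

#' @rdname nReflections
setMethod("nReflections", "MergedSet", function(x) nrow(x@hkl))
#' @rdname nReflections
setMethod("nReflections", "UnmergedSet", function(x) nrow(x@hkl))
#' @rdname nReflections
setMethod("nReflections", "CalcSet", function(x) nrow(x@hkl))

#' Truncate a reflection set at a high-resolution cutoff
#'
#' Retains exactly the records with d-spacing `>= dCutoff` (inclusive at
#' the boundary), computed from the set's own cell. `dCutoff = 0` is the
#' identity; an empty result is permitted.
#'
#' @param x A [MergedSet-class] or [UnmergedSet-class].
#' @param dCutoff High-resolution cutoff in Angstrom (>= 0).
#' @return An object of the same class.
#' @export
setGeneric("selectResolution", function(x, dCutoff) standardGeneric("selectResolution"))

#' Miller indices of a set
#' @param x A set with an `hkl` slot.
#' @return Integer matrix (n x 3).
#' @export
setGeneric("millerIndices", function(x) standardGeneric("millerIndices"))

#' @rdname millerIndices
setMethod("millerIndices", "MergedSet", function(x) x@hkl)
#' @rdname millerIndices
setMethod("millerIndices", "UnmergedSet", function(x) x@hkl)
#' @rdname millerIndices
setMethod("millerIndices", "CalcSet", function(x) x@hkl)

#' Atom table of a model
#' @param x An [AtomicModel-class].
#' @return data.frame of atoms (element, zeff, fractional x/y/z, occ, b).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
setMethod("atoms", "AtomicModel", function(x) x@atoms)

#' Free-flag set count of merged data
#' @param x A [MergedSet-class].
#' @return Integer k.
#' @export
setGeneric("flagCount", function(x) standardGeneric("flagCount"))

#' @rdname flagCount
setMethod("flagCount", "MergedSet", function(x) x@flagCount)

#' Ladder step table
#' @param x A [LadderResult-class].
#' @return data.frame of per-step paired-comparison records.
#' @export
setGeneric("ladderSteps", function(x) standardGeneric("ladderSteps"))

#' @rdname ladderSteps
setMethod("ladderSteps", "LadderResult", function(x) x@steps)

#' Cross-validation aggregate table
#' @param x A [CrossValResult-class].
#' @return data.frame of per-step mean/SD/SEM and rise/fall counts.
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

#' @rdname cvSummary
setMethod("cvSummary", "CrossValResult", function(x) x@summary)

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              object@a, object@b, object@c, object@alpha, object@beta, object@gamma))
})

setMethod("show", "ShellScheme", function(object) {
  e <- object@edges
  cat(sprintf("ShellScheme: %d shells from %.3f to %.3f A\n",
              length(e) - 1L, e[1], e[length(e)]))
})

setMethod("show", "MergedSet", function(object) {
  cat(sprintf("MergedSet: %d unique reflections (%s), %d free-flag sets\n",
              nrow(object@hkl),
              if (object@kind == "F") "amplitudes" else "intensities",
              object@flagCount))
  show(object@cell)
})

setMethod("show", "UnmergedSet", function(object) {
  cat(sprintf("UnmergedSet '%s': %d observations, %d unique reflections\n",
              object@label, nrow(object@hkl),
              length(unique(friedelKey(object@hkl)))))
  show(object@cell)
})

setMethod("show", "AtomicModel", function(object) {
  cat(sprintf("AtomicModel '%s': %d atoms, mean B = %.2f A^2\n",
              object@label, nrow(object@atoms), mean(object@atoms$b)))
  show(object@cell)
})

setMethod("show", "RefinementResult", function(object) {
  cat(sprintf("RefinementResult: cutoff %.3f A, %d cycles, scale %.4f, residual %.6g -> %.6g\n",
              object@cutoff, object@cycles, object@scale,
              object@trace[1], object@trace[length(object@trace)]))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "AgreementReport", function(object) {
  o <- object@overall
  cat(sprintf("AgreementReport at %.3f A (free set %d): Rwork=%.4f Rfree=%s Rgap=%s\n",
              object@dCutoff, object@freeSet, o$rWork,
              ifelse(is.na(o$rFree), "NA", sprintf("%.4f", o$rFree)),
              ifelse(is.na(o$rGap), "NA", sprintf("%.4f", o$rGap))))
})

setMethod("show", "LadderResult", function(object) {
  cat(sprintf("LadderResult: start %.3f A, %d steps, free set %d\n",
              object@startRes, nrow(object@steps), object@freeSet))
  if (nrow(object@steps))
    print(object@steps[, c("from", "to", "dRwork", "dRfree", "rGapA")])
})

setMethod("show", "CrossValResult", function(object) {
  cat(sprintf("CrossValResult: %d free sets, %d steps\n",
              object@k, nrow(object@summary)))
  print(object@summary)
})
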