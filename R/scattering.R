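## Direct-summation structure factors for point atoms with isotropic
## Gaussian displacement falloff.
##
## Fc(h) = sum_j occ_j * Z_j * exp(-B_j / (4 d_h^2)) * exp(2 pi i h.x_j)
##
## Point atoms (constant Z instead of tabulated form factors) keep the
## calculation analytic and exactly linear in the atoms while preserving
## every statistical property the paired-refinement protocol monitors;
## they are deliberately non-physical.

#' Calculate structure factors by direct summation
#'
#' @param model An [AtomicModel-class].
#' @param hkl Integer (n x 3) matrix of Miller indices (Friedel-reduced
#'   internally), or a [CalcSet-class]/[MergedSet-class] whose indices are
#'   used.
#' @param dMin Resolution limit recorded on the result (default: smallest
#'   d among the indices).
#' @return A [CalcSet-class] with complex Fc per Friedel-unique index.
#' @export
calcStructureFactors <- function(model, hkl, dMin = NULL) {
  if (is(hkl, "CalcSet") || is(hkl, "MergedSet") || is(hkl, "UnmergedSet"))
    hkl <- millerIndices(hkl)
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  if (nrow(hkl) == 0) stop("empty index list")
  hkl <- friedelReduce(hkl)
  storage.mode(hkl) <- "integer"
  d <- dSpacing(model@cell, hkl)
  at <- model@atoms
  ## n_refl x n_atom matrices; fine at desk scale
  phase <- 2 * pi * (hkl %*% t(as.matrix(at[, c("x", "y", "z")])))
  falloff <- exp(outer(-1 / (4 * d^2), at$b))  # exp(-B/(4 d^2))
  f <- falloff * rep(at$occ * at$zeff, each = nrow(hkl))
  fc <- complex(real = rowSums(f * cos(phase)), imaginary = rowSums(f * sin(phase)))
  if (is.null(dMin)) dMin <- min(d)
  new("CalcSet", cell = model@cell, hkl = hkl, fc = fc, dMin = dMin)
}

#' Structure-factor amplitudes of a CalcSet
#' @param x A [CalcSet-class].
#' @return Numeric vector |Fc|.
#' @export
amplitudes <- function(x) Mod(x@fc)

#' Write calculated structure factors as text
#'
#' Format: `# CELL ...` header then `h k l amplitude phase_deg` lines; the
#' exchange format of the external-backend adapter.
#'
#' @param x A [CalcSet-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeCalc <- function(x, path) {
  hdr <- c(sprintf("# CELL %.6g %.6g %.6g %.6g %.6g %.6g",
                   x@cell@a, x@cell@b, x@cell@c, x@cell@alpha, x@cell@beta, x@cell@gamma),
           "# h k l amplitude phase_deg")
  body <- sprintf("%d %d %d %.10g %.10g", x@hkl[, 1], x@hkl[, 2], x@hkl[, 3],
                  Mod(x@fc), Arg(x@fc) * 180 / pi)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read calculated structure factors written by [writeCalc()]
#'
#' @param path File path.
#' @return A [CalcSet-class].
#' @export
readCalc <- function(path) {
  lines <- readLines(path)
  cc <- grep("^\\s*#\\s*CELL", lines, value = TRUE)
  if (!length(cc)) stop("missing '# CELL' header in ", path)
  tok <- as.numeric(strsplit(trimws(sub("^\\s*#\\s*CELL", "", cc[1])), "\\s+")[[1]])
  cell <- unitCellNew(tok[1], tok[2], tok[3], tok[4], tok[5], tok[6])
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(dat), "\\s+"))), ncol = 5, byrow = TRUE)
  hkl <- m[, 1:3, drop = FALSE]; storage.mode(hkl) <- "integer"
  ph <- m[, 5] * pi / 180
  new("CalcSet", cell = cell, hkl = hkl,
      fc = complex(modulus = m[, 4], argument = ph),
      dMin = min(dSpacing(cell, hkl)))
}
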