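## Atomic model: PDB I/O, coordinate/ADP modification recipes, RMSD metrics.

## Electron counts for the elements the point-atom scattering model
## supports.
.elementZ <- c(H = 1, C = 6, N = 7, O = 8, NA. = 11, MG = 12, P = 15, S = 16,
               CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28,
               CU = 29, ZN = 30, SE = 34, BR = 35, I = 53)

elementZ <- function(sym) {
  z <- .elementZ[toupper(sub("^NA$", "NA.", sym))]
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(sym[is.na(z)]), collapse = ", "))
  unname(z)
}

#' Construct an atomic model
#'
#' @param cell A [UnitCell-class].
#' @param atoms data.frame with columns element, x, y, z (fractional
#'   coordinates), occ, b; a `zeff` electron-count column is derived from
#'   `element` if absent.
#' @param label Model label.
#' @return An [AtomicModel-class].
#' @export
atomicModel <- function(cell, atoms, label = "model") {
  if (!"zeff" %in% names(atoms)) atoms$zeff <- elementZ(atoms$element)
  atoms <- atoms[, c("element", "zeff", "x", "y", "z", "occ", "b")]
  rownames(atoms) <- NULL
  new("AtomicModel", cell = cell, atoms = atoms, label = label)
}

#' Fractional to Cartesian coordinates of a model
#' @param model An [AtomicModel-class].
#' @return n x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
cartesianCoords <- function(model) {
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  xyz %*% t(orthMatrix(model@cell))
}

#' Read a PDB file into an atomic model
#'
#' ATOM/HETATM records are parsed with `bio3d::read.pdb`; the mandatory
#' CRYST1 record supplies the unit cell and Cartesian coordinates are
#' converted to fractional under the standard orthogonalization convention
#' (a along x, b in the x-y plane). Files with ANISOU records are rejected:
#' only isotropic ADPs are supported.
#'
#' @param path PDB file path.
#' @param label Model label (default the file name).
#' @return An [AtomicModel-class].
#' @export
readPDB <- function(path, label = basename(path)) {
  lines <- readLines(path)
  if (any(startsWith(lines, "ANISOU")))
    stop("ANISOU records found in ", path, ": only isotropic ADPs are supported")
  cr <- lines[startsWith(lines, "CRYST1")]
  if (!length(cr)) stop("missing CRYST1 record in ", path)
  p <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                    substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                    substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  if (anyNA(p)) stop("malformed CRYST1 record in ", path)
  cell <- unitCellNew(p[1], p[2], p[3], p[4], p[5], p[6])
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  sym <- trimws(at$elesy)
  sym[!nzchar(sym) | is.na(sym)] <- substr(trimws(at$elety[!nzchar(sym) | is.na(sym)]), 1, 1)
  frac <- cbind(at$x, at$y, at$z) %*% t(solve(orthMatrix(cell)))
  atomicModel(cell,
              data.frame(element = toupper(sym), x = frac[, 1], y = frac[, 2],
                         z = frac[, 3], occ = at$o, b = at$b),
              label = label)
}

#' Write an atomic model as a PDB file
#'
#' Writes a CRYST1 record from the model's cell, then the atoms (Cartesian
#' coordinates, occupancy, isotropic B) through `bio3d::write.pdb`. A
#' write-read round trip preserves coordinates to the PDB fixed-decimal
#' precision (1e-3 Angstrom).
#'
#' @param model An [AtomicModel-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writePDB <- function(model, path) {
  cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                model@cell@a, model@cell@b, model@cell@c,
                model@cell@alpha, model@cell@beta, model@cell@gamma)
  writeLines(cr, path)
  xyz <- cartesianCoords(model)
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, append = TRUE,
                   xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   elety = model@atoms$element, resid = rep("UNK", n),
                   chain = rep("A", n), resno = seq_len(n),
                   o = model@atoms$occ, b = model@atoms$b,
                   elesy = model@atoms$element)
  invisible(path)
}

#' Perturb atomic coordinates
#'
#' Displaces every atom along an isotropically random direction with a
#' displacement magnitude drawn from an exponential distribution whose
#' mean equals `meanShift`, so the expected mean displacement is exactly
#' the requested value (the root-mean-square displacement is then
#' `sqrt(2) * meanShift`). Deterministic for a fixed seed; the cell is
#' unchanged and the input model is not modified.
#'
#' @param model An [AtomicModel-class].
#' @param meanShift Mean displacement in Angstrom (>= 0).
#' @param seed Integer seed.
#' @return A new [AtomicModel-class].
#' @export
perturbCoordinates <- function(model, meanShift, seed = 1L) {
  if (meanShift < 0) stop("meanShift must be >= 0")
  if (meanShift == 0) return(model)
  n <- nrow(model@atoms)
  withSeed(seed, {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    r <- stats::rexp(n, rate = 1 / meanShift)
    shift <- (v * r) %*% t(solve(orthMatrix(model@cell)))  # Cartesian -> fractional
    at <- model@atoms
    at$x <- at$x + shift[, 1]; at$y <- at$y + shift[, 2]; at$z <- at$z + shift[, 3]
    new("AtomicModel", cell = model@cell, atoms = at,
        label = paste0(model@label, "+perturbed"))
  })
}

#' Reset atomic displacement parameters
#'
#' `mode = "mean"` sets every B to the model's mean B (preserving the mean
#' exactly); `mode = "value"` sets every B to `value`.
#'
#' @param model An [AtomicModel-class].
#' @param mode "mean" or "value".
#' @param value Target B in square Angstrom (required for `mode = "value"`).
#' @return A new [AtomicModel-class].
#' @export
resetADP <- function(model, mode = c("mean", "value"), value = NULL) {
  mode <- match.arg(mode)
  at <- model@atoms
  if (mode == "mean") {
    at$b <- rep(mean(at$b), nrow(at))
  } else {
    if (is.null(value) || value <= 0) stop("explicit ADP value must be positive")
    at$b <- rep(as.numeric(value), nrow(at))
  }
  new("AtomicModel", cell = model@cell, atoms = at, label = model@label)
}

#' Shift all atomic displacement parameters
#'
#' Adds `delta` to every B; errors if any resulting B would be
#' non-positive.
#'
#' @param model An [AtomicModel-class].
#' @param delta Shift in square Angstrom.
#' @return A new [AtomicModel-class].
#' @export
shiftADP <- function(model, delta) {
  at <- model@atoms
  if (any(at$b + delta <= 0))
    stop("ADP shift of ", delta, " would make some B factors non-positive")
  at$b <- at$b + delta
  new("AtomicModel", cell = model@cell, atoms = at, label = model@label)
}

#' Coordinate RMSD between two models
#'
#' Root-mean-square Cartesian displacement over the identity atom pairing
#' (same atom count and order required); no superposition is performed,
#' because compared models share one crystal frame.
#'
#' @param model,reference [AtomicModel-class] objects with identical atom
#'   counts and order.
#' @return RMSD in Angstrom.
#' @export
rmsdCoordinates <- function(model, reference) {
  if (nrow(model@atoms) != nrow(reference@atoms))
    stop("models have different atom counts")
  d <- cartesianCoords(model) - cartesianCoords(reference)
  sqrt(mean(rowSums(d^2)))
}

#' ADP RMSD between two models
#'
#' Root-mean-square difference of the isotropic B factors over the
#' identity pairing.
#'
#' @param model,reference [AtomicModel-class] objects with identical atom
#'   counts and order.
#' @return RMS B difference in square Angstrom.
#' @export
rmsdADP <- function(model, reference) {
  if (nrow(model@atoms) != nrow(reference@atoms))
    stop("models have different atom counts")
  sqrt(mean((model@atoms$b - reference@atoms$b)^2))
}
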