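## Unit-cell geometry: constructors, orthogonalization, reciprocal metric,
## d-spacings.

#' Construct a unit cell
#'
#' @param a,b,c Cell edges in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees (default 90).
#' @return A validated [UnitCell-class].
#' @examples
#' unitCellNew(30, 35, 40)
#' @export
unitCellNew <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta), gamma = as.numeric(gamma))
}

#' Cell parameters as a named vector
#' @param cell A [UnitCell-class].
#' @return Named numeric vector (a, b, c, alpha, beta, gamma).
#' @export
cellParameters <- function(cell) {
  c(a = cell@a, b = cell@b, c = cell@c,
    alpha = cell@alpha, beta = cell@beta, gamma = cell@gamma)
}

#' Orthogonalization matrix of a cell
#'
#' Returns the 3x3 matrix M mapping fractional to Cartesian coordinates
#' (Angstrom) under the standard convention: a along x, b in the x-y plane.
#'
#' @param cell A [UnitCell-class].
#' @return 3x3 numeric matrix.
#' @export
orthMatrix <- function(cell) {
  ca <- cos(cell@alpha * pi / 180); cb <- cos(cell@beta * pi / 180)
  cg <- cos(cell@gamma * pi / 180); sg <- sin(cell@gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0,       cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0,       0,           cell@c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Cell volume
#' @param cell A [UnitCell-class].
#' @return Volume in cubic Angstrom.
#' @export
cellVolume <- function(cell) abs(det(orthMatrix(cell)))

## Reciprocal metric tensor G* = (M' M)^-1: h' G* h = 1/d^2.
reciprocalMetric <- function(cell) {
  m <- orthMatrix(cell)
  solve(crossprod(m))
}

#' d-spacing of Miller indices
#'
#' Bragg plane spacing d = (h' G* h)^(-1/2) with G* the reciprocal metric
#' tensor of the cell; valid for any (triclinic) cell and symmetric in
#' Friedel mates.
#'
#' @param cell A [UnitCell-class].
#' @param hkl Integer vector of length 3 or an (n x 3) matrix.
#' @return Numeric vector of d-spacings in Angstrom.
#' @examples
#' dSpacing(unitCellNew(10, 10, 10), c(1, 0, 0))  # 10
#' @export
dSpacing <- function(cell, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  if (ncol(hkl) != 3) stop("hkl must have three columns")
  if (any(rowSums(hkl != 0) == 0))
    stop("d-spacing undefined for the zero index (0,0,0)")
  g <- reciprocalMetric(cell)
  q <- rowSums((hkl %*% g) * hkl)  # 1/d^2
  1 / sqrt(q)
}
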