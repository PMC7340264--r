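## Friedel reduction, shell schemes, resolution selection and index
## enumeration.

#' Reduce Miller indices to Friedel-canonical form
#'
#' Maps (h,k,l) and (-h,-k,-l) to the same canonical representative: the
#' one whose first nonzero component is positive.
#'
#' @param hkl Integer vector of length 3 or an (n x 3) matrix.
#' @return Same shape as the input, canonicalised.
#' @examples
#' friedelReduce(c(-1, -2, -3))  # (1, 2, 3)
#' friedelReduce(c(0, -1, 2))    # (0, 1, -2)
#' @export
friedelReduce <- function(hkl) {
  vec <- is.null(dim(hkl))
  if (vec) hkl <- matrix(hkl, ncol = 3)
  if (any(rowSums(hkl != 0) == 0)) stop("cannot reduce the zero index")
  ## sign of the first nonzero component per row
  s <- sign(hkl[, 1])
  s[s == 0] <- sign(hkl[s == 0, 2, drop = TRUE])
  s[s == 0] <- sign(hkl[s == 0, 3, drop = TRUE])
  out <- hkl * s
  if (vec) out[1, ] else out
}

## String key for Friedel-unique grouping.
friedelKey <- function(hkl) {
  r <- friedelReduce(hkl)
  paste(r[, 1], r[, 2], r[, 3], sep = "_")
}

#' Build a resolution shell scheme
#'
#' Shells are contiguous intervals in d-spacing descending from `dStart`.
#' Either a constant `width` (default 0.05 Angstrom) or an explicit vector
#' of descending inner edges may be given; explicit edges override the
#' width. With a width, the last shell is truncated at `dFinal`.
#'
#' A reflection with d exactly equal to an interior edge belongs to the
#' shell below it in d (the higher-resolution side); the final edge is
#' inclusive, matching [selectResolution()]'s `d >= cutoff` rule.
#'
#' @param dStart Low-resolution end (largest d) in Angstrom.
#' @param dFinal High-resolution end (smallest d); required unless `edges`
#'   is given.
#' @param width Shell width in Angstrom (default 0.05).
#' @param edges Optional explicit descending inner edges (excluding
#'   `dStart`).
#' @return A [ShellScheme-class].
#' @examples
#' makeShells(2.4, edges = c(2.3, 2.2, 2.1, 2.0))  # 4 shells
#' makeShells(1.52, 1.44, width = 0.05)            # 1.52-1.47, 1.47-1.44
#' @export
makeShells <- function(dStart, dFinal = NULL, width = 0.05, edges = NULL) {
  if (!is.null(edges)) {
    if (any(diff(edges) >= 0)) stop("explicit shell edges must be strictly decreasing")
    if (edges[1] >= dStart) stop("shell edges must lie below dStart")
    return(new("ShellScheme", edges = c(dStart, edges)))
  }
  if (is.null(dFinal)) stop("either dFinal or explicit edges are required")
  if (!(dStart > dFinal && dFinal > 0)) stop("need dStart > dFinal > 0")
  if (width <= 0) stop("shell width must be positive")
  ## exact decimal-style arithmetic: count whole widths, truncate the last
  n <- floor((dStart - dFinal) / width + 1e-9)
  e <- dStart - width * seq_len(n)
  if (n == 0L || e[length(e)] > dFinal + 1e-9) e <- c(e, dFinal)
  else e[length(e)] <- dFinal
  new("ShellScheme", edges = c(dStart, e))
}

#' Shell edges
#' @param shells A [ShellScheme-class].
#' @return Descending numeric vector of d-spacing edges.
#' @export
shellEdges <- function(shells) shells@edges

#' Number of shells
#' @param shells A [ShellScheme-class].
#' @return Integer.
#' @export
nShells <- function(shells) length(shells@edges) - 1L

#' Assign d-spacings to shells
#'
#' Returns, for each d, the 1-based shell index under the scheme's
#' half-open convention (`[upper, lower)`, final shell closed), or NA for
#' values outside the scheme's range.
#'
#' @param shells A [ShellScheme-class].
#' @param d Numeric d-spacings.
#' @return Integer vector of shell indices (NA outside range).
#' @export
shellAssign <- function(shells, d) {
  e <- shells@edges
  k <- length(e)
  ## interval i: d in (e[i+1], e[i]] would be the closed-at-top convention;
  ## we want [e[i], e[i+1]) i.e. a point at an interior edge joins the
  ## lower-d (higher-resolution) shell, and the final edge is inclusive.
  idx <- rep(NA_integer_, length(d))
  inside <- d <= e[1] & d >= e[k]
  ## findInterval on -d with edges -e gives half-open [e_i, e_{i+1}) in d
  idx[inside] <- findInterval(-d[inside], -e, left.open = FALSE)
  idx[inside & d == e[k]] <- k - 1L  # final edge closed
  idx[idx == k] <- k - 1L
  idx[!inside] <- NA_integer_
  idx
}

#' @describeIn selectResolution Truncate merged data.
#' @export
setMethod("selectResolution", "MergedSet", function(x, dCutoff) {
  if (dCutoff < 0) stop("dCutoff must be >= 0")
  if (dCutoff == 0 || nrow(x@hkl) == 0) return(x)
  keep <- dSpacing(x@cell, x@hkl) >= dCutoff
  new("MergedSet", cell = x@cell, hkl = x@hkl[keep, , drop = FALSE],
      value = x@value[keep], sigma = x@sigma[keep], flag = x@flag[keep],
      kind = x@kind, flagCount = x@flagCount)
})

#' @describeIn selectResolution Truncate unmerged observations.
#' @export
setMethod("selectResolution", "UnmergedSet", function(x, dCutoff) {
  if (dCutoff < 0) stop("dCutoff must be >= 0")
  if (dCutoff == 0 || nrow(x@hkl) == 0) return(x)
  keep <- dSpacing(x@cell, x@hkl) >= dCutoff
  new("UnmergedSet", cell = x@cell, hkl = x@hkl[keep, , drop = FALSE],
      intensity = x@intensity[keep], sigma = x@sigma[keep], label = x@label)
})

#' Enumerate the Friedel-unique index sphere
#'
#' All Friedel-canonical Miller indices with d-spacing `>= dMin` for the
#' given cell (no space-group symmetry beyond Friedel reduction; data are
#' treated as P1). Used as the completeness denominator and by the
#' synthetic-data generator.
#'
#' @param cell A [UnitCell-class].
#' @param dMin High-resolution limit in Angstrom.
#' @param dMax Optional low-resolution limit (default Inf).
#' @return Integer matrix (n x 3) of canonical indices.
#' @export
enumerateUnique <- function(cell, dMin, dMax = Inf) {
  if (dMin <= 0) stop("dMin must be positive")
  hmax <- ceiling(cell@a / dMin) + 1L
  kmax <- ceiling(cell@b / dMin) + 1L
  lmax <- ceiling(cell@c / dMin) + 1L
  ## canonical half-space: h>0; or h==0 & k>0; or h==0 & k==0 & l>0
  g <- rbind(
    as.matrix(expand.grid(h = 1:hmax, k = -kmax:kmax, l = -lmax:lmax)),
    as.matrix(expand.grid(h = 0L, k = 1:kmax, l = -lmax:lmax)),
    as.matrix(expand.grid(h = 0L, k = 0L, l = 1:lmax)))
  storage.mode(g) <- "integer"
  d <- dSpacing(cell, g)
  g <- g[d >= dMin & d <= dMax, , drop = FALSE]
  dimnames(g) <- NULL
  g
}
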