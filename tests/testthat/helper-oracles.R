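## Independent brute-force oracles and fixture builders. Everything here is
## deliberately naive (explicit loops, no shared code with the package
## internals beyond the public constructors).

## Friedel-canonical key by explicit comparison.
naiveCanonical <- function(h, k, l) {
  v <- c(h, k, l)
  nz <- which(v != 0)[1]
  if (v[nz] < 0) v <- -v
  v
}

naiveKey <- function(hkl) {
  apply(hkl, 1, function(r) paste(naiveCanonical(r[1], r[2], r[3]), collapse = "_"))
}

## d-spacing via explicit reciprocal-basis construction: invert the
## orthogonalization matrix and take the norm of the scattering vector.
naiveD <- function(cell, hkl) {
  m <- orthMatrix(cell)
  rb <- solve(m)  # rows are the reciprocal basis vectors
  apply(matrix(hkl, ncol = 3), 1, function(h) {
    s <- rb[1, ] * 0
    s <- h[1] * rb[1, ] + h[2] * rb[2, ] + h[3] * rb[3, ]
    1 / sqrt(sum(s^2))
  })
}

## Naive per-group merging statistics for one set of observations
## (intensities i, sigmas s, group keys g). Returns per-unique rows.
naiveMerge <- function(i, s, g) {
  keys <- unique(g)
  out <- data.frame(key = keys, mean = NA_real_, sigma = NA_real_, n = NA_integer_)
  for (j in seq_along(keys)) {
    sel <- g == keys[j]
    out$mean[j] <- sum(i[sel]) / sum(sel)
    out$sigma[j] <- sqrt(sum(s[sel]^2)) / sum(sel)
    out$n[j] <- sum(sel)
  }
  out
}

## Naive Rmerge/Rmeas/Rpim over all observations with group keys g.
naiveRMetrics <- function(i, g) {
  keys <- unique(g)
  num1 <- num2 <- num3 <- den <- 0
  for (key in keys) {
    v <- i[g == key]
    n <- length(v)
    if (n < 2) next
    dev <- sum(abs(v - mean(v)))
    num1 <- num1 + dev
    num2 <- num2 + sqrt(n / (n - 1)) * dev
    num3 <- num3 + sqrt(1 / (n - 1)) * dev
    den <- den + sum(v)
  }
  if (den == 0) return(c(rMerge = NA_real_, rMeas = NA_real_, rPim = NA_real_))
  c(rMerge = num1 / den, rMeas = num2 / den, rPim = num3 / den)
}

## Naive CC1/2 for multiplicity-2 data: the split is deterministic (first
## stored observation of each unique to half A).
naiveCCHalfM2 <- function(i, g) {
  keys <- unique(g)
  ha <- hb <- numeric(0)
  for (key in keys) {
    v <- i[g == key]
    if (length(v) != 2) next
    ha <- c(ha, v[1]); hb <- c(hb, v[2])
  }
  if (length(ha) < 3 || sd(ha) == 0 || sd(hb) == 0) return(NA_real_)
  cor(ha, hb)
}

## Naive Friedel-unique enumeration by triple loop (small cells only).
naiveEnumerate <- function(cell, dmin) {
  hmax <- ceiling(cell@a / dmin) + 1
  kmax <- ceiling(cell@b / dmin) + 1
  lmax <- ceiling(cell@c / dmin) + 1
  out <- NULL
  for (h in -hmax:hmax) for (k in -kmax:kmax) for (l in -lmax:lmax) {
    if (h == 0 && k == 0 && l == 0) next
    v <- c(h, k, l)
    nz <- which(v != 0)[1]
    if (v[nz] < 0) next  # keep only the canonical representative
    if (naiveD(cell, matrix(v, 1)) >= dmin) out <- rbind(out, v)
  }
  out
}

## Naive direct-summation structure factor, double loop.
naiveFc <- function(model, hkl) {
  at <- atoms(model)
  d <- naiveD(unitCell(model), hkl)
  out <- complex(nrow(hkl))
  for (r in seq_len(nrow(hkl))) {
    acc <- 0 + 0i
    for (j in seq_len(nrow(at))) {
      f <- at$occ[j] * at$zeff[j] * exp(-at$b[j] / (4 * d[r]^2))
      ph <- 2 * pi * sum(hkl[r, ] * c(at$x[j], at$y[j], at$z[j]))
      acc <- acc + f * complex(real = cos(ph), imaginary = sin(ph))
    }
    out[r] <- acc
  }
  out
}

## Random valid unit cell (usually triclinic, occasionally orthogonal).
randomCell <- function() {
  repeat {
    ang <- runif(3, 70, 110)
    ca <- cos(ang[1] * pi / 180); cb <- cos(ang[2] * pi / 180); cg <- cos(ang[3] * pi / 180)
    if (1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg > 0.05) break
  }
  unitCellNew(runif(1, 8, 40), runif(1, 8, 40), runif(1, 8, 40),
              ang[1], ang[2], ang[3])
}

## Random unmerged set over a tiny cubic cell: <= nMax observations over a
## few uniques, multiplicity per unique drawn in 1..4.
randomUnmerged <- function(nMax = 50, cell = unitCellNew(8, 8, 8), mult = NULL) {
  idx <- as.matrix(expand.grid(h = 0:2, k = -1:2, l = -1:2))
  idx <- idx[rowSums(idx != 0) > 0, , drop = FALSE]
  idx <- friedelReduce(idx)
  idx <- idx[!duplicated(paste(idx[, 1], idx[, 2], idx[, 3])), , drop = FALSE]
  hkl <- NULL
  ord <- sample.int(nrow(idx))   # distinct uniques only
  i <- 0
  repeat {
    i <- i + 1
    u <- idx[ord[i], ]
    m <- if (is.null(mult)) sample(1:4, 1) else mult
    ## store some observations as the Friedel mate
    rows <- matrix(rep(u, m), ncol = 3, byrow = TRUE)
    fl <- runif(m) < 0.3
    rows[fl, ] <- -rows[fl, , drop = FALSE]
    hkl <- rbind(hkl, rows)
    if (nrow(hkl) >= nMax - 4 || i == nrow(idx)) break
  }
  n <- nrow(hkl)
  unmergedSet(cell, hkl, intensity = rnorm(n, 100, 30), sigma = runif(n, 1, 5))
}

## A quick small synthetic study used by several protocol tests.
smallStudy <- function(seed = 1, nAtoms = 30, dMin = 1.5, dInfo = 1.5,
                       mult = 2, nFlagSets = 4,
                       cell = unitCellNew(14, 15, 16)) {
  cfg <- generatorConfig(cell = cell, nAtoms = nAtoms, dMin = dMin,
                         multiplicity = mult, dInfo = dInfo, transition = 0.05,
                         nFlagSets = nFlagSets, seed = seed)
  truth <- generateTruth(cfg)
  dat <- generateData(truth, cfg)
  list(cfg = cfg, truth = truth, merged = dat$merged, unmerged = dat$unmerged)
}
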