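cubic8 <- unitCellNew(8, 8, 8)

test_that("intensity merging averages Friedel-reduced groups", {
  u <- unmergedSet(cubic8, rbind(c(1, 0, 0), c(-1, 0, 0)), c(10, 12), c(1, 1))
  m <- mergeIntensities(u)
  expect_equal(nrow(m), 1L)            # Friedel mates merged into one unique
  expect_equal(m$i, 11)
  expect_equal(m$sigma, sqrt(2) / 2)
  expect_equal(m$n, 2L)
  ## single observation passes through
  u1 <- unmergedSet(cubic8, rbind(c(2, 1, 0)), 7.5, 0.4)
  m1 <- mergeIntensities(u1)
  expect_equal(c(m1$i, m1$sigma, m1$n), c(7.5, 0.4, 1))
  expect_error(mergeIntensities(unmergedSet(cubic8, matrix(integer(0), ncol = 3),
                                            numeric(0), numeric(0))), "empty")
})

test_that("R metrics match hand arithmetic and exclude singly observed uniques", {
  sh <- makeShells(9, 1, width = 8)
  u <- unmergedSet(cubic8, rbind(c(1, 0, 0), c(1, 0, 0)), c(10, 12), c(1, 1))
  r <- rMetrics(u, sh)
  ov <- r[r$shell == "overall", ]
  expect_equal(ov$rMerge, 2 / 22)
  expect_equal(ov$rMeas, 2 * sqrt(2) / 22)
  expect_equal(ov$rPim, 2 / 22)
  ## identical observations give zero
  u0 <- unmergedSet(cubic8, rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0)),
                    c(5, 5, 9, 9), rep(1, 4))
  r0 <- rMetrics(u0, sh)
  r0 <- r0[r0$shell == "overall", ]
  expect_equal(c(r0$rMerge, r0$rMeas, r0$rPim), c(0, 0, 0))
  ## all uniques singly observed -> missing, not zero
  u1 <- unmergedSet(cubic8, rbind(c(1, 0, 0), c(0, 1, 0)), c(5, 9), c(1, 1))
  r1 <- rMetrics(u1, sh)
  expect_true(all(is.na(r1[r1$shell == "overall", c("rMerge", "rMeas", "rPim")])))
})

test_that("merging statistics agree with brute-force recomputation on random sets", {
  sh <- makeShells(9, 2, width = 3.5)
  set.seed(101)
  for (rep in 1:60) {
    u <- randomUnmerged(50)
    key <- naiveKey(u@hkl)
    ## merge
    ref <- naiveMerge(u@intensity, u@sigma, key)
    m <- mergeIntensities(u)
    expect_equal(m$i, ref$mean, tolerance = 1e-12)
    expect_equal(m$sigma, ref$sigma, tolerance = 1e-12)
    expect_equal(m$n, ref$n)
    ## overall R metrics
    mine <- rMetrics(u, sh)
    ov <- mine[mine$shell == "overall", ]
    ref2 <- naiveRMetrics(u@intensity, key)
    expect_equal(c(ov$rMerge, ov$rMeas, ov$rPim), unname(ref2), tolerance = 1e-12)
    ## invariants: rPim <= rMeas, rMerge <= rMeas
    ok <- !is.na(mine$rMeas)
    expect_true(all(mine$rPim[ok] <= mine$rMeas[ok] + 1e-15))
    expect_true(all(mine$rMerge[ok] <= mine$rMeas[ok] + 1e-15))
  }
})

test_that("with multiplicity 2 everywhere, Rpim equals Rmerge and CC1/2 is deterministic", {
  sh <- makeShells(9, 2, width = 7)
  set.seed(33)
  for (rep in 1:10) {
    u <- randomUnmerged(40, mult = 2)
    r <- rMetrics(u, sh)
    ok <- !is.na(r$rMerge)
    expect_equal(r$rPim[ok], r$rMerge[ok], tolerance = 1e-15)
    cc <- ccHalf(u, sh, seed = 5)
    ref <- naiveCCHalfM2(u@intensity, naiveKey(u@hkl))
    ovcc <- cc$ccHalf[cc$shell == "overall"]
    if (is.na(ref)) expect_true(is.na(ovcc))
    else expect_equal(ovcc, ref, tolerance = 1e-12)
  }
})

test_that("CC1/2 reproduces the hand-computed three-unique example and guards", {
  sh <- makeShells(9, 1, width = 8)
  hkl <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 1))
  u <- unmergedSet(cubic8, hkl, c(10, 12, 5, 5, 1, 3), rep(1, 6))
  cc <- ccHalf(u, sh, seed = 1)
  ## halves A = (10,5,1), B = (12,5,3): hand Pearson 41.3333/42.6198 = 0.96982
  expect_equal(cc$ccHalf[cc$shell == "overall"], 0.969816, tolerance = 1e-5)
  ## both halves identical -> exactly 1
  u2 <- unmergedSet(cubic8, hkl, c(10, 10, 5, 5, 1, 1), rep(1, 6))
  cc2 <- ccHalf(u2, sh)
  expect_equal(cc2$ccHalf[cc2$shell == "overall"], 1)
  ## two contributing uniques only -> missing
  u3 <- unmergedSet(cubic8, hkl[1:4, ], c(10, 12, 5, 6), rep(1, 4))
  cc3 <- ccHalf(u3, sh)
  expect_true(is.na(cc3$ccHalf[cc3$shell == "overall"]))
  ## same seed -> identical, different seed may differ (n > 2 splits)
  u4 <- randomUnmerged(40, mult = 3)
  expect_identical(ccHalf(u4, sh, seed = 9), ccHalf(u4, sh, seed = 9))
})

test_that("correlation significance implements the one-sided Student test", {
  expect_true(ccSignificance(0.99, 100))
  expect_false(ccSignificance(0.0, 1000))
  expect_true(is.na(ccSignificance(0.5, 2)))
  ## numeric oracle: direct tail computation for cc = 0.5, n = 30
  t <- 0.5 * sqrt(28 / (1 - 0.25))
  pRef <- pt(t, 28, lower.tail = FALSE)
  expect_equal(unname(ccSignificance(0.5, 30, alpha = pRef * 1.01)), TRUE)
  expect_equal(unname(ccSignificance(0.5, 30, alpha = pRef * 0.99)), FALSE)
})

test_that("CC* transform has the right fixed points, monotonicity and guards", {
  expect_equal(ccStar(1), 1)
  expect_equal(ccStar(0), 0)
  expect_equal(ccStar(0.5), sqrt(1 / 1.5), tolerance = 1e-12)
  ## monotone increasing on [0, 1]
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(ccStar(x)) > 0))
  expect_true(is.na(ccStar(-0.5)))
  expect_error(ccStar(-1), "exceed")
})

test_that("completeness counts against the Friedel-unique sphere", {
  cell <- unitCellNew(6, 6, 6)
  sh <- makeShells(7, 2.5, width = 2)
  all <- enumerateUnique(cell, 2.5, 7)
  full <- unmergedSet(cell, all, intensity = rep(10, nrow(all)),
                      sigma = rep(1, nrow(all)))
  comp <- shellCompleteness(full, sh)
  expect_true(all(comp$completeness == 100))
  ## remove half the uniques of the first shell -> 50% there
  d <- dSpacing(cell, all)
  idx <- shellAssign(sh, d)
  inS1 <- which(idx == 1L)
  drop <- inS1[seq_len(floor(length(inS1) / 2))]
  part <- unmergedSet(cell, all[-drop, , drop = FALSE],
                      intensity = rep(10, nrow(all) - length(drop)),
                      sigma = rep(1, nrow(all) - length(drop)))
  comp2 <- shellCompleteness(part, sh)
  expect_equal(comp2$completeness[1],
               100 * (length(inS1) - length(drop)) / length(inS1))
  ## empty shell -> 0
  onlyS1 <- unmergedSet(cell, all[inS1, , drop = FALSE],
                        intensity = rep(10, length(inS1)), sigma = rep(1, length(inS1)))
  expect_equal(shellCompleteness(onlyS1, sh)$completeness[2], 0)
})

test_that("the merging table is internally consistent and deterministic", {
  set.seed(55)
  u <- randomUnmerged(60)
  sh <- makeShells(9, 2, width = 3.5)
  tab <- mergingTable(u, sh, seed = 4)
  expect_equal(nrow(tab), nShells(sh) + 1L)   # shells + overall
  ## multiplicity x nUnique = nObservations on every row
  ok <- tab$nUnique > 0
  expect_equal(tab$multiplicity[ok] * tab$nUnique[ok], tab$nObservations[ok])
  ## determinism at fixed seed
  expect_identical(tab, mergingTable(u, sh, seed = 4))
  ## undefined entries are NA, never 0 (no n>=2 unique in an empty shell)
  expect_true(all(is.na(tab$rMeas) | tab$rMeas >= 0))
})

test_that("mean I/sigma declines as the planted noise fraction grows", {
  ## statistical trend over seeds: more additive noise -> lower <I/sigma>
  highShell <- function(noise, seed) {
    cfg <- generatorConfig(cell = unitCellNew(14, 15, 16), nAtoms = 15, dMin = 1.6,
                           multiplicity = 3, noiseShell = noise, dInfo = 1.6,
                           seed = seed)
    dat <- generateData(generateTruth(cfg), cfg)
    sh <- makeShells(3, 1.6, width = 0.7)
    tab <- mergingTable(dat$unmerged, sh, seed = 1)
    tab$meanIOverSigma[tab$shell == "overall"]
  }
  lo <- vapply(1:3, function(s) highShell(0.05, s), numeric(1))
  hi <- vapply(1:3, function(s) highShell(0.60, s), numeric(1))
  expect_true(mean(hi) < mean(lo))
})
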