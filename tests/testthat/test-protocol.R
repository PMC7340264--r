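## Small self-consistent study shared by the ladder tests: informative
## noise-free data so every added shell should help.
protoFixture <- function(seed = 14, dMin = 1.4) {
  m <- generateTruth(generatorConfig(cell = unitCellNew(12, 13, 14),
                                     nAtoms = 20, seed = seed))
  hkl <- enumerateUnique(unitCell(m), dMin)
  fc <- calcStructureFactors(m, hkl, dMin = dMin)
  set.seed(seed)
  flags <- sample.int(4L, nrow(hkl), replace = TRUE) - 1L
  merged <- mergedSet(unitCell(m), hkl, Mod(fc@fc), rep(1, nrow(hkl)),
                      flags, kind = "F", nFlagSets = 4L)
  list(truth = m, merged = merged)
}

test_that("step annotations encode the published interpretation rules", {
  expect_match(annotateStep(0.001, -0.002), "beneficial")
  expect_match(annotateStep(0.002, 0.0001), "less overfitting")
  expect_match(annotateStep(-0.001, 0.003), "no improvement")
  expect_match(annotateStep(0.0001, 0.0002), "no significant change")
  expect_match(annotateStep(0.001, NA), "unavailable")
})

test_that("ladder validation rejects degenerate cutoff sequences", {
  fx <- protoFixture()
  start <- perturbCoordinates(fx$truth, 0.1, seed = 1)
  expect_error(runLadder(start, fx$merged, 2.0, cutoffs = c(2.0, 1.8)),
               "strictly below")
  expect_error(runLadder(start, fx$merged, 2.0, cutoffs = c(1.8, 1.9)),
               "strictly decreasing")
})

test_that("with informative noise-free data the ladder improves the model at every step", {
  fx <- protoFixture()
  start <- perturbCoordinates(fx$truth, 0.12, seed = 7)
  resA <- refineModel(start, fx$merged, 2.0, nCycles = 60)
  lad <- runLadder(resA, fx$merged, 2.0, cutoffs = c(1.8, 1.6, 1.4),
                   nCycles = 60)
  s <- ladderSteps(lad)
  expect_equal(nrow(s), 3L)
  ## continuity: each step starts where the previous ended
  expect_equal(s$from, c(2.0, 1.8, 1.6))
  expect_equal(s$to, c(1.8, 1.6, 1.4))
  ## noise-free informative data: Rfree never deteriorates
  expect_true(all(s$dRfree <= 1e-6))
  ## Rgap identity on the reported curve
  expect_equal(s$rGapA, s$rFreeA - s$rWorkA, tolerance = 1e-15)
  ## rmsd to truth is non-increasing as informative shells are added
  rmsds <- vapply(lad@models, function(r) rmsdCoordinates(r@model, fx$truth),
                  numeric(1))
  expect_true(all(diff(rmsds) <= 1e-6))
})

test_that("CCwork stays below CC* on well-fitted synthetic data with real noise", {
  st <- smallStudy(seed = 23, nAtoms = 25, dMin = 1.5, dInfo = 1.5, mult = 4)
  start <- degradeModel(st$truth, st$cfg, perturb = 0.1)
  resA <- refineModel(start, st$merged, 1.9, nCycles = 60)
  lad <- runLadder(resA, st$merged, 1.9, cutoffs = c(1.7, 1.5),
                   unmerged = st$unmerged, nCycles = 60, seed = 2)
  sh <- lad@shellStats
  ok <- !is.na(sh$ccWork) & !is.na(sh$ccStar)
  expect_gt(sum(ok), 0)
  expect_true(all(sh$ccWork[ok] < sh$ccStar[ok] + 0.02))
  ## merging table attached and aligned with the ladder shells
  expect_false(is.null(lad@merging))
})

test_that("cross-validation aggregation matches hand arithmetic", {
  v <- rbind(c(0.01, -0.02), c(0.03, -0.01), c(-0.01, 0.03))
  agg <- cvAggregate(v)
  expect_equal(agg$mean, c(0.01, 0.0), tolerance = 1e-15)
  expect_equal(agg$sd, c(0.02, sd(c(-0.02, -0.01, 0.03))), tolerance = 1e-15)
  expect_equal(agg$sem, agg$sd / sqrt(3), tolerance = 1e-15)
  ## rises/falls: (+,+,-) -> 2 up, 1 down
  expect_equal(agg$rises[1], 2)
  expect_equal(agg$falls[1], 1)
})

test_that("complete cross-validation runs one ladder per free set and aggregates", {
  fx <- protoFixture(seed = 31, dMin = 1.6)
  expect_error(runCompleteCV(fx$truth,
    mergedSet(unitCell(fx$truth), fx$merged@hkl, fx$merged@value,
              fx$merged@sigma, rep(0L, nReflections(fx$merged)), nFlagSets = 1L),
    2.0, c(1.8)), "flagCount >= 2")

  start <- perturbCoordinates(fx$truth, 0.1, seed = 2)
  cv <- runCompleteCV(start, fx$merged, 2.0, cutoffs = c(1.8, 1.6),
                      modifications = list(perturb = 0.05, resetAdp = "mean"),
                      nCycles = 40, seed = 9)
  expect_equal(cv@k, 4L)
  expect_length(cv@results, 4L)
  sm <- cvSummary(cv)
  expect_equal(nrow(sm), 2L)
  ## SEM column is SD/sqrt(k) exactly
  expect_equal(sm$semDRfree, sm$sdDRfree / sqrt(4), tolerance = 1e-15)
  ## mean of per-set values matches the reported mean
  perSet <- vapply(cv@results, function(r) r@steps$dRfree, numeric(2))
  expect_equal(sm$meanDRfree, rowMeans(perSet), tolerance = 1e-12)
  expect_equal(sm$rises + sm$falls <= 4, rep(TRUE, 2))
  ## per-set ladders used their own free set
  expect_equal(vapply(cv@results, function(r) r@freeSet, integer(1)), 0:3)
})

test_that("report bundles are complete and byte-identical across reruns", {
  fx <- protoFixture(seed = 40, dMin = 1.6)
  start <- perturbCoordinates(fx$truth, 0.08, seed = 3)
  resA <- refineModel(start, fx$merged, 2.0, nCycles = 30)
  lad <- runLadder(resA, fx$merged, 2.0, cutoffs = c(1.8, 1.7, 1.65, 1.6),
                   nCycles = 30, seed = 5)
  d1 <- tempfile("rep1"); d2 <- tempfile("rep2")
  f1 <- writeReports(lad, d1)
  expect_true(file.exists(file.path(d1, "steps.csv")))
  expect_true(file.exists(file.path(d1, "report.html")))
  ## 4 steps -> 4 rows
  steps <- read.csv(file.path(d1, "steps.csv"))
  expect_equal(nrow(steps), 4L)
  ## per-step models written (start + 4 steps)
  expect_length(grep("^model_step", basename(f1)), 5L)
  ## rerunning the identical analysis reproduces the CSVs byte for byte
  lad2 <- runLadder(refineModel(start, fx$merged, 2.0, nCycles = 30),
                    fx$merged, 2.0, cutoffs = c(1.8, 1.7, 1.65, 1.6),
                    nCycles = 30, seed = 5)
  writeReports(lad2, d2)
  expect_identical(readLines(file.path(d1, "steps.csv")),
                   readLines(file.path(d2, "steps.csv")))
  expect_identical(readLines(file.path(d1, "shells.csv")),
                   readLines(file.path(d2, "shells.csv")))
})
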