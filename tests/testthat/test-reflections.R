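test_that("d-spacing matches the reciprocal-basis construction on simple and triclinic cells", {
  cubic <- unitCellNew(10, 10, 10)
  expect_equal(dSpacing(cubic, c(1, 0, 0)), 10)
  expect_equal(dSpacing(cubic, c(1, 1, 0)), 10 / sqrt(2))
  ## monoclinic cell, full triclinic formula against the independent
  ## reciprocal-basis oracle
  mono <- unitCellNew(45.20, 73.10, 52.57, 90, 109.25, 90)
  expect_equal(dSpacing(mono, c(2, 0, 0)), naiveD(mono, c(2, 0, 0)), tolerance = 1e-12)
  ## property: 100 random valid cells x random indices, 1e-10 relative
  set.seed(42)
  for (i in 1:100) {
    cell <- randomCell()
    hkl <- matrix(sample(-8:8, 15, replace = TRUE), ncol = 3)
    hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
    expect_equal(dSpacing(cell, hkl), naiveD(cell, hkl), tolerance = 1e-10)
  }
  ## Friedel symmetry of d
  expect_equal(dSpacing(mono, c(3, -2, 1)), dSpacing(mono, c(-3, 2, -1)))
  expect_error(dSpacing(cubic, c(0, 0, 0)), "zero index")
})

test_that("Friedel reduction maps mates to one canonical index", {
  expect_equal(friedelReduce(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(friedelReduce(c(-1, -2, -3)), c(1, 2, 3))
  expect_equal(friedelReduce(c(0, -1, 2)), c(0, 1, -2))
  expect_equal(friedelReduce(c(0, 0, -5)), c(0, 0, 5))
  ## involution-free: applying twice changes nothing
  set.seed(1)
  m <- matrix(sample(-6:6, 300, replace = TRUE), ncol = 3)
  m <- m[rowSums(m != 0) > 0, ]
  expect_identical(friedelReduce(friedelReduce(m)), friedelReduce(m))
  ## mates collapse to the same key
  expect_identical(friedelKey(m), friedelKey(-m))
  expect_error(friedelReduce(c(0, 0, 0)), "zero")
})

test_that("shell schemes partition the resolution range without gaps", {
  ## explicit edges, the typical ladder call
  sh <- makeShells(2.4, edges = c(2.3, 2.2, 2.1, 2.0))
  expect_equal(nShells(sh), 4L)
  expect_equal(shellEdges(sh), c(2.4, 2.3, 2.2, 2.1, 2.0))
  ## constant width, exact division and truncation
  expect_equal(shellEdges(makeShells(1.5, 1.4, width = 0.05)), c(1.5, 1.45, 1.4))
  expect_equal(shellEdges(makeShells(1.52, 1.44, width = 0.05)), c(1.52, 1.47, 1.44))
  expect_error(makeShells(2.4, edges = c(2.2, 2.3)), "decreasing")
  expect_error(makeShells(1.4, 1.5, width = 0.05), "dStart > dFinal")

  ## assignment convention: boundary reflection joins the
  ## higher-resolution shell; final edge inclusive; outside -> NA
  expect_equal(shellAssign(sh, c(2.4, 2.35, 2.3, 2.05, 2.0)), c(1L, 1L, 2L, 4L, 4L))
  expect_true(is.na(shellAssign(sh, 2.5)))
  expect_true(is.na(shellAssign(sh, 1.9)))
  ## no gaps/overlaps: every point in range lands in exactly one shell
  d <- seq(2.0, 2.4, by = 0.001)
  idx <- shellAssign(sh, d)
  expect_false(anyNA(idx))
  expect_true(all(idx >= 1 & idx <= 4))
})

test_that("resolution selection is inclusive, idempotent and monotone", {
  cell <- unitCellNew(10, 10, 10)
  hkl <- rbind(c(1, 0, 0), c(2, 0, 0), c(5, 0, 0))  # d = 10, 5, 2
  ms <- mergedSet(cell, hkl, value = c(10, 20, 30), sigma = c(1, 1, 1),
                  flag = c(0L, 1L, 0L), nFlagSets = 2L)
  expect_equal(nReflections(selectResolution(ms, 4)), 2L)
  expect_equal(nReflections(selectResolution(ms, 5)), 2L)   # inclusive boundary
  expect_equal(nReflections(selectResolution(ms, 11)), 0L)
  expect_identical(selectResolution(ms, 0), ms)
  ## cutting at B then at A >= B equals cutting at A
  expect_equal(selectResolution(selectResolution(ms, 3), 5)@hkl,
               selectResolution(ms, 5)@hkl)
  expect_equal(selectResolution(selectResolution(ms, 5), 5)@hkl,
               selectResolution(ms, 5)@hkl)
  us <- unmergedSet(cell, hkl, intensity = 1:3, sigma = rep(1, 3))
  expect_equal(nReflections(selectResolution(us, 4)), 2L)
})

test_that("merged text format round-trips bit-exactly and validates input", {
  cell <- unitCellNew(12, 13, 14, 90, 101.5, 90)
  set.seed(7)
  n <- 1000
  hkl <- unique(matrix(sample(-9:9, 3 * 4 * n, replace = TRUE), ncol = 3))
  hkl <- friedelReduce(hkl[rowSums(hkl != 0) > 0, ])
  hkl <- hkl[!duplicated(paste(hkl[, 1], hkl[, 2], hkl[, 3])), ][1:n, ]
  ms <- mergedSet(cell, hkl, value = round(runif(n, 1, 500), 4),
                  sigma = round(runif(n, 0.1, 5), 4),
                  flag = sample(0:4, n, replace = TRUE), kind = "I",
                  nFlagSets = 5L)
  f <- tempfile(fileext = ".hkl")
  writeMerged(ms, f)
  back <- readMerged(f)
  expect_identical(back@hkl, ms@hkl)
  expect_identical(back@value, ms@value)
  expect_identical(back@sigma, ms@sigma)
  expect_identical(back@flag, ms@flag)
  expect_identical(back@kind, "I")
  expect_identical(back@flagCount, 5L)
  ## second write is byte-identical
  f2 <- tempfile(fileext = ".hkl")
  writeMerged(back, f2)
  expect_identical(readLines(f), readLines(f2))

  ## flag inference and header errors
  tf <- tempfile()
  writeLines(c("# CELL 10 10 10 90 90 90", "# KIND F",
               "1 0 0 12.5 1.0 0", "0 1 0 9.1 0.9 1", "0 0 1 7.7 1.1 0"), tf)
  expect_equal(flagCount(readMerged(tf)), 2L)
  writeLines(c("# KIND F", "1 0 0 12.5 1.0 0"), tf)
  expect_error(readMerged(tf), "CELL")
  writeLines(c("# CELL 10 10 10 90 90 90"), tf)
  expect_error(readMerged(tf), "no reflections")
  writeLines(c("# CELL 10 10 10 90 90 90", "1 0 0 12.5 1.0 0.5"), tf)
  expect_error(readMerged(tf), "integer")
  writeLines(c("# CELL 10 10 10 90 90 90", "1 0 0 12.5 -1.0 0"), tf)
  expect_error(readMerged(tf), "sigma")
})

test_that("unmerged XDS-ASCII-style parsing honours headers and drops bad sigmas", {
  tf <- tempfile()
  writeLines(c("!FORMAT=XDS_ASCII",
               "!UNIT_CELL_CONSTANTS= 10 11 12 90 90 90",
               "1 0 0 100.0 3.0",
               "-1 0 0 104.0 3.1",
               "1 0 0 98.0 2.9",
               "0 1 0 -5.0 2.0",   # negative intensity retained
               "0 1 0 55.0 2.0",
               "0 -1 0 60.0 2.1"), tf)
  us <- readUnmerged(tf)
  expect_equal(nReflections(us), 6L)
  expect_equal(cellParameters(unitCell(us))[["b"]], 11)
  expect_true(any(us@intensity < 0))

  ## sigma <= 0 dropped with a reported count
  writeLines(c("!UNIT_CELL_CONSTANTS= 10 10 10 90 90 90",
               "1 0 0 100.0 3.0", "1 0 0 101.0 0.0"), tf)
  expect_message(us2 <- readUnmerged(tf), "dropped 1")
  expect_equal(nReflections(us2), 1L)

  ## cell from argument when the file has none; error when neither
  writeLines(c("! headers only", "2 0 0 50 1.5"), tf)
  expect_error(readUnmerged(tf), "no unit cell")
  us3 <- readUnmerged(tf, cell = unitCellNew(9, 9, 9))
  expect_equal(nReflections(us3), 1L)
  ## write-read round trip
  f2 <- tempfile()
  writeUnmerged(us, f2)
  back <- readUnmerged(f2)
  expect_identical(back@hkl, us@hkl)
  expect_identical(back@intensity, us@intensity)
})

test_that("the Friedel-unique enumeration matches a naive triple loop", {
  cell <- unitCellNew(6, 7, 8)
  mine <- enumerateUnique(cell, 2.5)
  ref <- naiveEnumerate(cell, 2.5)
  expect_equal(nrow(mine), nrow(ref))
  expect_setequal(paste(mine[, 1], mine[, 2], mine[, 3]),
                  paste(ref[, 1], ref[, 2], ref[, 3]))
})

test_that("container validity rejects inconsistent data", {
  cell <- unitCellNew(10, 10, 10)
  expect_error(unitCellNew(-1, 10, 10), "positive")
  expect_error(unitCellNew(10, 10, 10, 10, 10, 170), "metric")
  expect_error(mergedSet(cell, rbind(c(1, 0, 0)), 10, -1, 0L), "sigma")
  expect_error(mergedSet(cell, rbind(c(1, 0, 0), c(-1, 0, 0)), c(1, 2),
                         c(1, 1), c(0L, 0L)), "duplicate")
  expect_error(mergedSet(cell, rbind(c(0, 0, 0)), 1, 1, 0L), "zero|valid")
})
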