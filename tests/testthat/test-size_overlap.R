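test_that("segment profile of a geometric series is flat", {
  p <- segmentProfile(BodySizeTable(c("a", "b", "c"), c(1, 10, 100)))
  expect_equal(p@segments, c(1, 1))
  expect_equal(p@varianceSegments, 0)
  expect_equal(p@minSegment, 1)
})

test_that("segment profile matches hand arithmetic on {8, 16, 30} m", {
  p <- segmentProfile(BodySizeTable(c("a", "b", "c"), c(8, 16, 30)))
  expect_equal(p@segments, c(log10(2), log10(30 / 16)), tolerance = 1e-12)
  expect_equal(p@minSegment, log10(1.875), tolerance = 1e-12)
})

test_that("profile is invariant to input order and species labels", {
  sizes <- c(12, 8, 25, 17, 9.5)
  base <- segmentProfile(BodySizeTable(paste0("s", 1:5), sizes))
  for (k in 1:5) {
    perm <- sample(5)
    p <- segmentProfile(BodySizeTable(paste0("x", 1:5), sizes[perm]))
    expect_equal(p@segments, base@segments)
    expect_equal(p@minSegment, base@minSegment)
  }
})

test_that("log10 segments are invariant to rescaling all sizes", {
  sz <- makeSizes(8, "uniform", seed = 21)
  base <- segmentProfile(sz)
  for (c in c(0.5, 2, 7.3)) {
    scaled <- BodySizeTable(speciesNames(sz), bodyLengths(sz) * c)
    expect_equal(segmentProfile(scaled)@segments, base@segments,
                 tolerance = 1e-12)
  }
})

test_that("guards: too few species, non-positive sizes, ties", {
  expect_error(segmentProfile(BodySizeTable(c("a", "b"), c(1, 2))),
               ">= 3")
  expect_no_error(
    segmentProfile(BodySizeTable(c("a", "b", "c"), c(1, 2, 3)),
                   transform = "identity"))
  expect_warning(
    segmentProfile(BodySizeTable(c("a", "b", "c", "d"), c(2, 5, 5, 9))),
    "tied")
  # NA sizes are excluded with a warning, then the count rule applies
  expect_warning(
    p <- segmentProfile(BodySizeTable(letters[1:4], c(2, 4, 8, NA))),
    "without size estimates")
  expect_length(p@segments, 2)
  expect_error(suppressWarnings(
    segmentProfile(BodySizeTable(letters[1:4], c(2, 4, NA, NA)))), ">= 3")
})

test_that("n = 3 uniform null recovers the closed-form mean of min segment", {
  # endpoints 0 and 1 on the log scale: E[min(U, 1 - U)] = 1/4
  sz <- BodySizeTable(c("a", "b", "c"), c(1, 3, 10))
  r <- nullModelSizeOverlap(sz, metric = "min", iterations = 20000,
                            seed = 8)
  expect_equal(mean(nullValues(r)), 0.25, tolerance = 0.02)
})

test_that("evenly spaced sizes sit at the metric boundaries", {
  ev <- makeSizes(10, "even_log")
  rv <- nullModelSizeOverlap(ev, metric = "variance", iterations = 500,
                             seed = 3)
  # variance 0 is the unique minimum: pLower attains its floor
  expect_equal(observedStat(rv), 0)
  expect_equal(pLower(rv), 1 / 501)
  rm_ <- nullModelSizeOverlap(ev, metric = "min", iterations = 500,
                              seed = 3)
  # even spacing maximizes the smallest gap given fixed endpoints
  expect_lte(pUpper(rm_), 1 / 100)
})

test_that("size-overlap null is deterministic under a fixed seed", {
  sz <- makeSizes(12, "uniform", seed = 2)
  r1 <- nullModelSizeOverlap(sz, "variance", iterations = 400, seed = 11)
  r2 <- nullModelSizeOverlap(sz, "variance", iterations = 400, seed = 11)
  expect_identical(nullValues(r1), nullValues(r2))
})

test_that("pool mode resamples from a larger source pool", {
  pool <- makeSizes(30, "uniform", seed = 4)
  assemblage <- BodySizeTable(paste0("a", 1:8),
                              bodyLengths(pool)[seq(1, 30, by = 4)])
  r <- nullModelSizeOverlap(assemblage, "min", iterations = 300,
                            mode = "pool", pool = pool, seed = 5)
  expect_length(nullValues(r), 300)
  expect_gt(r@nullSd, 0)
  expect_error(
    nullModelSizeOverlap(assemblage, "min", iterations = 10,
                         mode = "pool", pool = assemblage, seed = 1),
    "larger than the assemblage")
})

test_that("uniform assemblages are flagged structured near the alpha rate", {
  hits <- 0
  reps <- 150
  for (k in seq_len(reps)) {
    sz <- makeSizes(15, "uniform", seed = 5000 + k)
    r <- nullModelSizeOverlap(sz, "min", iterations = 400,
                              seed = 6000 + k)
    if (pUpper(r) <= 0.05) hits <- hits + 1
  }
  # one-sided 99.5% binomial bound around 0.05
  expect_lte(hits, qbinom(0.995, reps, 0.05))
})
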