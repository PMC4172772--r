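test_that("CSV round trip preserves cells and labels exactly", {
  set.seed(42)
  for (k in 1:5) {
    occ <- randomIncidence(sample(3:9, 1), sample(3:9, 1))
    m <- IncidenceMatrix(occ)
    f <- withr::local_tempfile(fileext = ".csv")
    writeIncidenceCsv(m, f)
    m2 <- suppressWarnings(readIncidenceCsv(f))
    expect_identical(occurrenceMatrix(m2), occurrenceMatrix(m))
  }
})

test_that("cell parsing is strict 0/1 and errors name the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,s1,s2", "a,1,0", "b,0,2"), f)
  expect_error(readIncidenceCsv(f), "non-binary cell '2'.*'b'.*'s2'")
  writeLines(c("species,s1,s2", "a,1,0", "a,0,1"), f)
  expect_error(readIncidenceCsv(f), "duplicate species")
  writeLines(c("species,s1,s1", "a,1,0", "b,0,1"), f)
  expect_error(readIncidenceCsv(f), "duplicate site")
  # whitespace around cells is tolerated, other text is not
  writeLines(c("species,s1,s2", "a, 1 ,0", "b,0,1"), f)
  expect_identical(sum(occurrenceMatrix(readIncidenceCsv(f))), 2L)
})

test_that("a 2x2 identity-pattern file loads with 2 occurrences", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,s1,s2", "a,1,0", "b,0,1"), f)
  m <- readIncidenceCsv(f)
  expect_identical(nSpecies(m), 2L)
  expect_identical(sum(occurrenceMatrix(m)), 2L)
})

test_that("IncidenceMatrix validity rejects non-binary cells", {
  occ <- matrix(c(1, 2, 0, 1), 2, 2,
                dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(IncidenceMatrix(occ), "0 or 1")
})

test_that("packaged fixture has the published structure", {
  fx <- titanosaurFixtures()
  m <- fx$incidence
  expect_identical(nSpecies(m), 23L)
  expect_identical(nSites(m), 14L)
  expect_identical(sum(occurrenceMatrix(m)), 33L)
  mp <- margins(m)
  expect_identical(unname(colTotals(mp)),
                   c(4L, 7L, 1L, 5L, 1L, 2L, 3L, 3L, 1L, 1L, 2L, 1L, 1L, 1L))
  expect_identical(rowTotals(mp)[["Antarctosaurus wichmannianus"]], 4L)
  expect_identical(colTotals(mp)[["Anacleto"]], 7L)
  expect_identical(colTotals(mp)[["Allen"]], 5L)
})

test_that("fixture size tables carry the published extremes", {
  for (mode in c("recorded", "synthetic")) {
    sz <- titanosaurFixtures(sizes = mode)$sizes
    v <- bodyLengths(sz, dropNA = TRUE)
    expect_equal(unname(v[["Rocasaurus muniozi"]]), 8)
    expect_equal(unname(v[["Puertasaurus reuili"]]), 30)
    expect_equal(min(v), 8)
    expect_equal(max(v), 30)
  }
  # the recorded table invents nothing beyond the two anchors
  rec <- bodyLengths(titanosaurFixtures()$sizes)
  expect_identical(sum(!is.na(rec)), 2L)
  # the synthetic stand-in is complete
  syn <- bodyLengths(titanosaurFixtures(sizes = "synthetic")$sizes)
  expect_false(anyNA(syn))
})

test_that("margins sum invariant holds and all-zero margins are handled", {
  set.seed(7)
  for (k in 1:20) {
    m <- IncidenceMatrix(randomIncidence(sample(2:8, 1), sample(2:8, 1)))
    mp <- margins(m)
    expect_identical(sum(rowTotals(mp)), sum(colTotals(mp)))
  }
  zero <- IncidenceMatrix(matrix(0L, 3, 3,
    dimnames = list(paste0("sp", 1:3), paste0("s", 1:3))))
  mp <- margins(zero)
  expect_identical(unname(rowTotals(mp)), c(0L, 0L, 0L))
  expect_identical(unname(colTotals(mp)), c(0L, 0L, 0L))
})

test_that("species-value readers validate their input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,count", "a,3", "b,1"), f)
  expect_identical(unname(abundanceCounts(readAbundanceCsv(f))), c(3L, 1L))
  writeLines(c("species,count", "a,3", "b,x"), f)
  expect_error(readAbundanceCsv(f), "non-numeric")
  writeLines(c("species,length_m", "a,10", "b,NA", "c,12"), f)
  expect_identical(sum(is.na(bodyLengths(readBodySizeCsv(f)))), 1L)
  writeLines(c("species,length_m", "a,-3", "b,2", "c,4"), f)
  expect_error(readBodySizeCsv(f), "non-positive")
})
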