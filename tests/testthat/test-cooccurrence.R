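test_that("checkerboard units follow (ri - s)(rj - s)", {
  expect_equal(checkerboardUnits(4, 3, 2), 2)
  expect_equal(checkerboardUnits(4, 4, 4), 0)   # s = ri
  expect_equal(checkerboardUnits(c(2, 5), c(3, 5), c(0, 1)), c(6, 16))
  expect_error(checkerboardUnits(2, 3, 3), "exceed")
})

test_that("fixture pair Antarctosaurus x Neuquensaurus has CU 4", {
  pc <- pairCooccurrence(titanosaurFixtures()$incidence)
  row <- pc[pc$speciesI == "Antarctosaurus wichmannianus" &
            pc$speciesJ == "Neuquensaurus australis", ]
  expect_identical(nrow(row), 1L)
  expect_equal(row$ri, 4)
  expect_equal(row$rj, 4)
  expect_equal(row$s, 2)   # Anacleto and Palacio
  expect_equal(row$cu, 4)
})

test_that("C-score handles the degenerate textbook patterns", {
  ident <- IncidenceMatrix(matrix(c(1L, 0L, 0L, 1L), 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(cScore(ident), 1)
  expect_identical(checkerboardPairCount(ident), 1L)
  same <- IncidenceMatrix(matrix(c(1L, 1L, 0L, 0L, 1L, 1L), 2, 3,
    dimnames = list(c("a", "b"), c("x", "y", "z"))))
  expect_equal(cScore(same, dropEmpty = FALSE), 0)
  expect_identical(checkerboardPairCount(same, dropEmpty = FALSE), 0L)
  single <- IncidenceMatrix(matrix(1L, 1, 2,
    dimnames = list("a", c("x", "y"))))
  expect_error(cScore(single), "at least 2 species")
})

test_that("C-score equals the brute-force oracle on random matrices", {
  set.seed(101)
  for (k in 1:200) {
    occ <- randomIncidence(sample(2:8, 1), sample(2:8, 1),
                           fill = runif(1, 0.2, 0.8))
    m <- IncidenceMatrix(occ)
    expect_equal(cScore(m, dropEmpty = FALSE), bruteCscore(occ))
    expect_equal(checkerboardPairCount(m, dropEmpty = FALSE),
                 brutePairCount(occ))
  }
})

test_that("C-score matches an independent dissimilarity-based computation", {
  skip_if_not_installed("vegan")
  occ <- occurrenceMatrix(titanosaurFixtures()$incidence)
  d <- vegan::designdist(occ, "(A-J)*(B-J)", terms = "binary")
  expect_equal(cScore(titanosaurFixtures()$incidence), mean(d))
})

test_that("C-score is invariant under row and column permutations", {
  set.seed(33)
  occ <- randomIncidence(7, 6)
  occ[rowSums(occ) == 0, 1] <- 1L   # avoid empty-row warnings
  base <- cScore(IncidenceMatrix(occ))
  for (k in 1:10) {
    perm <- occ[sample(nrow(occ)), sample(ncol(occ))]
    expect_equal(cScore(IncidenceMatrix(perm)), base)
  }
})

test_that("all-zero rows/columns are dropped with a warning by default", {
  occ <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L), 3, 3,
                dimnames = list(paste0("sp", 1:3), paste0("s", 1:3)))
  m <- IncidenceMatrix(occ)
  expect_warning(v1 <- cScore(m), "all-zero")
  expect_equal(v1, cScore(IncidenceMatrix(occ[1:2, , drop = FALSE]),
                          dropEmpty = FALSE))
  # keeping them changes the mean (degenerate pairs enter the denominator)
  expect_equal(cScore(m, dropEmpty = FALSE), bruteCscore(occ))
})

test_that("a sequential swap step flips checkerboards and nothing else", {
  ident <- IncidenceMatrix(matrix(c(1L, 0L, 0L, 1L), 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))
  # the only submatrix is a checkerboard: repeated steps alternate states
  set.seed(5)
  cur <- ident
  states <- character(3)
  for (k in 1:3) {
    st <- sequentialSwapStep(cur)
    expect_true(st$swapped)
    cur <- st$matrix
    states[k] <- paste(occurrenceMatrix(cur), collapse = "")
  }
  expect_identical(states[1], "0110")
  expect_identical(states[2], "1001")
  expect_identical(states[3], "0110")
  full <- IncidenceMatrix(matrix(1L, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))
  st <- sequentialSwapStep(full)
  expect_false(st$swapped)
  expect_identical(occurrenceMatrix(st$matrix), occurrenceMatrix(full))
})

test_that("swap steps conserve both margins on arbitrary matrices", {
  set.seed(71)
  for (k in 1:20) {
    m <- IncidenceMatrix(randomIncidence(sample(3:7, 1), sample(3:7, 1)))
    before <- marginsOf(m)
    for (step in 1:50) m <- sequentialSwapStep(m)$matrix
    expect_identical(marginsOf(m), before)
  }
})

test_that("null model is deterministic under a fixed seed", {
  m <- titanosaurFixtures()$incidence
  r1 <- nullModelCscore(m, iterations = 300, burnIn = 3000, seed = 17)
  r2 <- nullModelCscore(m, iterations = 300, burnIn = 3000, seed = 17)
  expect_identical(nullValues(r1), nullValues(r2))
  expect_identical(pUpper(r1), pUpper(r2))
})

test_that("add-one tail probabilities count ties toward the tail", {
  tp <- assemblageNull:::.tailProbs(2, c(0.5, 1, 1.5))
  expect_equal(tp$pUpper, 1 / 4)     # observed above all 3 null values
  expect_equal(tp$pLower, 1)
  tp <- assemblageNull:::.tailProbs(1, c(1, 1, 2))
  expect_equal(tp$pUpper, 1)         # ties count as >= observed
  expect_equal(tp$pLower, 3 / 4)
  # observed strictly greater than 999 null draws -> p = 1/1000
  tp <- assemblageNull:::.tailProbs(5, runif(999))
  expect_equal(tp$pUpper, 1 / 1000)
})

test_that("a perfectly nested matrix yields a degenerate null", {
  nested <- makeNested(5, 6)
  expect_warning(r <- nullModelCscore(nested, iterations = 50, burnIn = 100,
                                      seed = 1),
                 "degenerate")
  expect_true(r@degenerate)
  expect_equal(r@nullSd, 0)
  expect_true(is.na(sesValue(r)))
})

test_that("strong segregation is detected by the null model", {
  cb <- makeCheckerboard(nPairs = 5, sitesPerSpecies = 5)
  r <- nullModelCscore(cb, iterations = 1000, burnIn = 10000, seed = 4)
  expect_lte(pUpper(r), 0.01)
  expect_gt(sesValue(r), 2)
})
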