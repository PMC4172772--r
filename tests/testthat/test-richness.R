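test_that("frequency tallies count singletons and doubletons", {
  tf <- tallyFrequencies(AbundanceVector(c(a = 1, b = 1, c = 2, d = 5)))
  expect_identical(tf, list(sobs = 4L, f1 = 2L, f2 = 1L))
  tf <- tallyFrequencies(AbundanceVector(c(a = 3, b = 4, c = 7)))
  expect_identical(tf$f1, 0L)
  expect_identical(tf$f2, 0L)
  gen <- makeAbundances(sobs = 10, f1 = 4, f2 = 2, seed = 5)
  k <- abundanceCounts(gen)
  # direct count oracle against the generator
  expect_identical(tallyFrequencies(gen),
                   list(sobs = length(k), f1 = sum(k == 1L),
                        f2 = sum(k == 2L)))
  expect_identical(tallyFrequencies(gen)[c("f1", "f2")],
                   list(f1 = 4L, f2 = 2L))
})

test_that("Chao1 point estimate follows the formula and its fallbacks", {
  est <- chao1Estimate(makeAbundances(10, 4, 2, seed = 1))
  expect_equal(est@chao1, 14.0)   # sobs + f1^2/(2 f2)
  expect_false(est@biasCorrected)
  # f2 = 0: bias-corrected fallback sobs + f1 (f1 - 1) / 2
  est <- chao1Estimate(makeAbundances(5, 3, 0, seed = 1))
  expect_equal(est@chao1, 8.0)
  expect_true(est@biasCorrected)
  # f1 = 0: estimate collapses to sobs and the CI degenerates
  est <- chao1Estimate(AbundanceVector(c(a = 3, b = 5, c = 9)))
  expect_equal(est@chao1, 3)
  expect_equal(c(est@ciLow, est@ciHigh), c(3, 3))
})

test_that("Chao1 is monotone in f1 and the CI contains the estimate", {
  prev <- -Inf
  for (f1 in 0:6) {
    est <- chao1Estimate(makeAbundances(12, f1, 3, seed = 2))
    expect_gte(est@chao1, prev)
    prev <- est@chao1
    expect_gte(est@chao1, est@sobs)
    expect_lte(est@ciLow, est@chao1 + 1e-9)
    expect_gte(est@ciHigh, est@chao1 - 1e-9)
    expect_gte(est@ciLow, 0)
  }
})

test_that("accumulation curve reaches Sobs and is deterministic by seed", {
  a <- makeAbundances(sobs = 20, f1 = 8, f2 = 4, seed = 3)
  c1 <- accumulationCurve(a, nRand = 100, seed = 9)
  c2 <- accumulationCurve(a, nRand = 100, seed = 9)
  expect_identical(c1@meanSobs, c2@meanSobs)
  expect_identical(c1@meanChao1, c2@meanChao1)
  # at the maximal level every permutation has seen every species
  expect_equal(tail(c1@meanSobs, 1), 20)
  expect_true(all(diff(c1@meanSobs) >= 0))
})

test_that("single-species accumulation is flat at 1", {
  a <- AbundanceVector(c(only = 7L))
  cv <- accumulationCurve(a, nRand = 20, seed = 1)
  expect_true(all(cv@meanSobs == 1))
})

test_that("accumulation beyond the record total needs replacement", {
  a <- AbundanceVector(c(a = 2L, b = 3L))
  expect_error(accumulationCurve(a, nRand = 5, levels = 1:10),
               "without replacement")
  cv <- accumulationCurve(a, nRand = 5, levels = 1:10, replacement = TRUE,
                          seed = 1)
  expect_length(cv@meanSobs, 10)
})

test_that("mean Chao1 approaches the true pool richness as samples grow", {
  set.seed(31)
  sTrue <- 30
  meanAt <- function(n, reps = 60) {
    mean(replicate(reps, {
      counts <- table(sample.int(sTrue, n, replace = TRUE))
      chao1Estimate(AbundanceVector(
        setNames(as.integer(counts), paste0("s", names(counts))))) @chao1
    }))
  }
  small <- meanAt(40)
  large <- meanAt(400)
  expect_lt(abs(large - sTrue), abs(small - sTrue) + 0.5)
  expect_lt(abs(large - sTrue), 1)
})
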