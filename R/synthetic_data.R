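#' @include size_overlap.R
NULL

#' Maximally segregated (checkerboard) incidence matrix
#'
#' Builds `2 * nPairs` species over two disjoint site blocks of
#' `sitesPerSpecies` sites each: odd-numbered species occupy the first
#' block, even-numbered species the second. Each within-pair comparison is
#' a perfect checkerboard with `CU = sitesPerSpecies^2`; with
#' `nPairs = 1, sitesPerSpecies = 1` this is the 2x2 identity pattern.
#'
#' @param nPairs number of species pairs (>= 1).
#' @param sitesPerSpecies sites occupied by every species (row total).
#' @param seed accepted for interface uniformity; the construction is
#'   deterministic.
#' @return An [IncidenceMatrix-class] of dimension
#'   `2 * nPairs` x `2 * sitesPerSpecies`.
#' @examples
#' cScore(makeCheckerboard(5, 5))
#' @export
makeCheckerboard <- function(nPairs, sitesPerSpecies = 1, seed = NULL) {
  stopifnot(nPairs >= 1, sitesPerSpecies >= 1)
  nSpecies <- 2L * as.integer(nPairs)
  nSites <- 2L * as.integer(sitesPerSpecies)
  occ <- matrix(0L, nSpecies, nSites,
                dimnames = list(sprintf("sp%02d", seq_len(nSpecies)),
                                sprintf("site%02d", seq_len(nSites))))
  block1 <- seq_len(sitesPerSpecies)
  block2 <- sitesPerSpecies + seq_len(sitesPerSpecies)
  occ[seq(1, nSpecies, by = 2), block1] <- 1L
  occ[seq(2, nSpecies, by = 2), block2] <- 1L
  IncidenceMatrix(occ)
}

#' Perfectly nested incidence matrix
#'
#' Row i occupies the first `nSites - i + 1` sites, so occupied-site sets
#' form a chain: every pair shares `s = min(r_i, r_j)` sites, every CU is
#' 0, and the C-score is exactly 0. Useful as the aggregated extreme
#' opposite the checkerboard generator — note such a matrix has no
#' swappable submatrix, so the fixed-fixed null is degenerate on it.
#'
#' @param nSpecies number of species (<= nSites).
#' @param nSites number of sites.
#' @param seed accepted for interface uniformity; deterministic.
#' @return An [IncidenceMatrix-class].
#' @export
makeNested <- function(nSpecies, nSites, seed = NULL) {
  stopifnot(nSpecies >= 2, nSpecies <= nSites)
  occ <- matrix(0L, nSpecies, nSites,
                dimnames = list(sprintf("sp%02d", seq_len(nSpecies)),
                                sprintf("site%02d", seq_len(nSites))))
  for (i in seq_len(nSpecies)) occ[i, seq_len(nSites - i + 1)] <- 1L
  IncidenceMatrix(occ)
}

#' Margin-matched randomization of a template matrix
#'
#' Applies `nSwaps` successful sequential swaps to a copy of the template;
#' the result has exactly the template's row and column totals but (for a
#' long enough chain) an otherwise randomized occupancy pattern.
#'
#' @param template an [IncidenceMatrix-class].
#' @param nSwaps number of successful swaps to apply (0 returns the
#'   template unchanged).
#' @param seed optional RNG seed.
#' @return An [IncidenceMatrix-class] with the template's margins. If the
#'   template has no swappable submatrix it is returned unchanged with a
#'   warning.
#' @examples
#' fx <- titanosaurFixtures()
#' r <- makeRandomMargins(fx$incidence, nSwaps = 1000, seed = 1)
#' identical(rowTotals(margins(r)), rowTotals(margins(fx$incidence)))
#' @export
makeRandomMargins <- function(template, nSwaps, seed = NULL) {
  stopifnot(is(template, "IncidenceMatrix"), nSwaps >= 0)
  if (nSwaps == 0) return(template)
  occ <- occurrenceMatrix(template)
  if (checkerboardPairCount(template, dropEmpty = FALSE) == 0) {
    warning("template has no swappable submatrix; returned unchanged")
    return(template)
  }
  res <- withSeed(seed,
    cpp_swap_chain(occ, as.integer(nSwaps), as.double(nSwaps) * 1e5 + 1e6))
  if (res$successes < nSwaps)
    warning(sprintf("only %d of %d requested swaps achieved",
                    res$successes, as.integer(nSwaps)))
  out <- res$matrix
  dimnames(out) <- dimnames(occ)
  IncidenceMatrix(out)
}

#' Abundance vector with prescribed singleton and doubleton counts
#'
#' Exactly `f1` species receive count 1 and `f2` species count 2; the
#' remaining species receive counts `3 + Geometric(1/3)` (mean 5). Only
#' (f1, f2) matter to Chao1, so the tail distribution is cosmetic.
#'
#' @param sobs total number of species (>= f1 + f2).
#' @param f1,f2 target singleton and doubleton counts.
#' @param seed optional RNG seed.
#' @return An [AbundanceVector-class] whose [tallyFrequencies()] recover
#'   (sobs, f1, f2) exactly.
#' @examples
#' tallyFrequencies(makeAbundances(23, 10, 5, seed = 1))
#' @export
makeAbundances <- function(sobs, f1, f2, seed = NULL) {
  stopifnot(sobs >= 1, f1 >= 0, f2 >= 0)
  if (f1 + f2 > sobs) stop("f1 + f2 cannot exceed sobs")
  rest <- sobs - f1 - f2
  counts <- withSeed(seed,
    c(rep(1L, f1), rep(2L, f2),
      if (rest > 0) 3L + stats::rgeom(rest, prob = 1 / 3) else integer(0)))
  AbundanceVector(stats::setNames(counts, sprintf("sp%02d", seq_len(sobs))))
}

#' Body-size spectra with controllable spacing
#'
#' Generates n body lengths in meters inside `rangeM`:
#' \describe{
#'   \item{even_log}{exactly geometric between the endpoints — the log10
#'     segments are all equal and their variance is 0 (maximally even).}
#'   \item{uniform}{log10 sizes drawn uniformly between the log endpoints —
#'     the unstructured reference.}
#'   \item{clustered}{two tight Gaussian clumps (sd = 2% of the log range)
#'     near the endpoints — minimal spacing within clumps, one large gap.}
#' }
#'
#' @param n number of species (>= 3).
#' @param pattern "even_log", "uniform" or "clustered".
#' @param rangeM numeric (min, max) lengths in meters, both positive.
#' @param seed optional RNG seed.
#' @return A [BodySizeTable-class].
#' @examples
#' segmentProfile(makeSizes(4, "even_log", c(8, 30)))
#' @export
makeSizes <- function(n, pattern = c("even_log", "uniform", "clustered"),
                      rangeM = c(8, 30), seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(n >= 3, length(rangeM) == 2, rangeM[1] > 0,
            rangeM[1] < rangeM[2])
  lo <- log10(rangeM[1]); hi <- log10(rangeM[2])
  logs <- withSeed(seed, switch(pattern,
    even_log = seq(lo, hi, length.out = n),
    uniform = stats::runif(n, lo, hi),
    clustered = {
      nLow <- ceiling(n / 2)
      sdClump <- 0.02 * (hi - lo)
      cl <- c(stats::rnorm(nLow, lo, sdClump),
              stats::rnorm(n - nLow, hi, sdClump))
      pmin(pmax(cl, lo - 3 * sdClump), hi + 3 * sdClump)
    }))
  BodySizeTable(sprintf("sp%02d", seq_len(n)), 10^logs)
}
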