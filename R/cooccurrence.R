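#' @include richness.R
NULL

#' Checkerboard units of a species pair
#'
#' `CU = (r_i - S)(r_j - S)`, where `r_i` and `r_j` are the two species'
#' row totals and `S` is the number of sites occupied by both. CU counts
#' the mutually exclusive site pairs the two species form; it is zero
#' exactly when one species' sites contain the other's.
#'
#' @param ri,rj row totals of the two species; vectorized.
#' @param s number of shared sites; must satisfy `s <= min(ri, rj)`.
#' @return Numeric vector of checkerboard-unit counts.
#' @examples
#' checkerboardUnits(4, 3, 2)
#' @export
checkerboardUnits <- function(ri, rj, s) {
  if (any(s > pmin(ri, rj)))
    stop("s cannot exceed min(ri, rj)")
  if (any(c(ri, rj, s) < 0)) stop("counts must be non-negative")
  (ri - s) * (rj - s)
}

# Drop all-zero rows/columns (warning), shared by the co-occurrence entry
# points; CU for an absent species is degenerate and deflates the mean.
.dropEmpty <- function(occ, dropEmpty) {
  if (!dropEmpty) return(occ)
  rs <- rowSums(occ); cs <- colSums(occ)
  if (any(rs == 0)) {
    warning(sprintf("dropping %d all-zero species row(s)", sum(rs == 0)))
    occ <- occ[rs > 0, , drop = FALSE]
  }
  if (any(cs == 0)) {
    warning(sprintf("dropping %d all-zero site column(s)", sum(cs == 0)))
    occ <- occ[, colSums(occ) > 0, drop = FALSE]
  }
  occ
}

# Pairwise CU values for all unordered species pairs, as a vector.
.pairCU <- function(occ) {
  r <- rowSums(occ)
  S <- tcrossprod(occ)           # S[i, j] = sites shared by i and j
  ri <- matrix(r, nrow(occ), nrow(occ))
  cu <- (ri - S) * (t(ri) - S)
  cu[upper.tri(cu)]
}

#' @describeIn cScore mean CU over all R(R-1)/2 unordered pairs of the
#'   occurrence matrix; every pair contributes, including CU = 0 pairs.
#' @export
setMethod("cScore", "IncidenceMatrix", function(m, dropEmpty = TRUE) {
  occ <- .dropEmpty(occurrenceMatrix(m), dropEmpty)
  if (nrow(occ) < 2) stop("need at least 2 species")
  mean(.pairCU(occ))
})

#' @describeIn checkerboardPairCount number of unordered pairs with CU > 0
#' @export
setMethod("checkerboardPairCount", "IncidenceMatrix",
          function(m, dropEmpty = TRUE) {
  occ <- .dropEmpty(occurrenceMatrix(m), dropEmpty)
  if (nrow(occ) < 2) stop("need at least 2 species")
  sum(.pairCU(occ) > 0)
})

#' Pairwise co-occurrence table
#'
#' Row totals, shared-site counts and checkerboard units for every
#' unordered species pair.
#'
#' @param m an [IncidenceMatrix-class].
#' @param dropEmpty drop all-zero rows/columns first (with a warning).
#' @return data.frame with columns speciesI, speciesJ, ri, rj, s, cu.
#' @export
pairCooccurrence <- function(m, dropEmpty = TRUE) {
  stopifnot(is(m, "IncidenceMatrix"))
  occ <- .dropEmpty(occurrenceMatrix(m), dropEmpty)
  if (nrow(occ) < 2) stop("need at least 2 species")
  r <- rowSums(occ)
  S <- tcrossprod(occ)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  data.frame(speciesI = rownames(occ)[i], speciesJ = rownames(occ)[j],
             ri = r[i], rj = r[j], s = S[upper.tri(S)],
             cu = checkerboardUnits(r[i], r[j], S[upper.tri(S)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One sequential-swap step
#'
#' Picks two distinct rows and two distinct columns uniformly at random; if
#' the selected 2x2 submatrix is a checkerboard (diagonal 1s and 0s in
#' either orientation) it is flipped, otherwise the matrix is returned
#' unchanged. Row and column totals are identical before and after in all
#' cases — this is the elementary move of the fixed-fixed null model.
#'
#' @param m an [IncidenceMatrix-class] with >= 2 species and >= 2 sites.
#' @return A list with `matrix` (the possibly-updated
#'   [IncidenceMatrix-class]) and `swapped` (logical).
#' @examples
#' m <- IncidenceMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("a", "b"), c("x", "y"))))
#' sequentialSwapStep(m)$swapped
#' @export
sequentialSwapStep <- function(m) {
  stopifnot(is(m, "IncidenceMatrix"))
  occ <- occurrenceMatrix(m)
  if (nrow(occ) < 2 || ncol(occ) < 2) stop("need at least a 2 x 2 matrix")
  rows <- sample.int(nrow(occ), 2)
  cols <- sample.int(ncol(occ), 2)
  sub <- occ[rows, cols]
  swapped <- FALSE
  if (sub[1, 1] == sub[2, 2] && sub[1, 2] == sub[2, 1] &&
      sub[1, 1] != sub[1, 2]) {
    occ[rows, cols] <- sub[, 2:1]
    swapped <- TRUE
  }
  list(matrix = IncidenceMatrix(occ), swapped = swapped)
}

#' Fixed-fixed sequential-swap null-model test of the C-score
#'
#' Tests the observed C-score against the distribution of C-scores of
#' margin-matched random matrices. The null chain starts from the observed
#' matrix, runs `burnIn` attempted swaps, then records the C-score once per
#' `thin` successful swaps, `iterations` times. Tail probabilities use the
#' add-one correction `p = (1 + #{null >= obs}) / (1 + iterations)` with
#' ties counted toward the tail; the standardized effect size
#' `(obs - null mean)/null sd` is reported alongside. Spatial segregation
#' shows up as a large C-score, so `pUpper` is the structure tail.
#'
#' A matrix with no swappable 2x2 checkerboard submatrix (e.g. perfectly
#' nested) cannot be randomized under fixed-fixed margins; the result is
#' flagged `degenerate` with null sd 0 and SES NA.
#'
#' @param m an [IncidenceMatrix-class].
#' @param iterations number of recorded null matrices (default 10000).
#' @param burnIn attempted swaps discarded before recording (default 30000).
#' @param thin successful swaps between recorded matrices (default 1).
#' @param seed optional RNG seed (results are reproducible given a seed).
#' @param dropEmpty drop all-zero rows/columns first (with a warning); they
#'   can never participate in a swap and deflate the C-score mean.
#' @return A [NullModelResult-class]; margins of every recorded matrix are
#'   verified against the observed margins inside the chain.
#' @examples
#' m <- makeCheckerboard(nPairs = 3, sitesPerSpecies = 3, seed = 1)
#' nullModelCscore(m, iterations = 200, burnIn = 2000, seed = 1)
#' @export
nullModelCscore <- function(m, iterations = 10000, burnIn = 30000,
                            thin = 1, seed = NULL, dropEmpty = TRUE) {
  stopifnot(is(m, "IncidenceMatrix"), iterations >= 1, burnIn >= 0,
            thin >= 1)
  occ <- .dropEmpty(occurrenceMatrix(m), dropEmpty)
  if (nrow(occ) < 2 || ncol(occ) < 2)
    stop("need at least a 2 x 2 matrix after dropping empty margins")
  mm <- IncidenceMatrix(occ)
  observed <- cScore(mm, dropEmpty = FALSE)
  if (checkerboardPairCount(mm, dropEmpty = FALSE) == 0) {
    warning("matrix has no swappable submatrix; null model is degenerate")
    return(.makeNullResult("c_score", observed,
                           rep(observed, iterations), iterations, burnIn,
                           thin, seed, degenerate = TRUE))
  }
  chain <- withSeed(seed,
    cpp_null_cscore(occ, as.double(burnIn), as.integer(iterations),
                    as.integer(thin), 1e7))
  if (chain$exhausted)
    stop("swap chain stalled; matrix is effectively unswappable")
  if (chain$margin_violations > 0)
    stop("internal error: margin conservation violated")
  .makeNullResult("c_score", observed, chain$null_values, iterations,
                  burnIn, thin, seed)
}

#' Histogram of a null distribution with the observed value marked
#'
#' @param x a [NullModelResult-class].
#' @param ... passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plotNullDistribution <- function(x, ...) {
  stopifnot(is(x, "NullModelResult"))
  graphics::hist(nullValues(x), breaks = 30,
                 main = paste("null distribution of", x@statisticName),
                 xlab = x@statisticName, col = "grey85", border = "white",
                 ...)
  graphics::abline(v = observedStat(x), lwd = 2)
  invisible(x)
}
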