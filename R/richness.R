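#' @include data_model.R
NULL

#' Tally observed richness, singletons and doubletons
#'
#' @param a an [AbundanceVector-class].
#' @return A list with `sobs` (species with >= 1 record), `f1` (species with
#'   exactly one record) and `f2` (species with exactly two).
#' @examples
#' tallyFrequencies(AbundanceVector(c(a = 1, b = 1, c = 2, d = 5)))
#' @export
tallyFrequencies <- function(a) {
  stopifnot(is(a, "AbundanceVector"))
  k <- abundanceCounts(a)
  if (length(k) == 0) stop("empty abundance vector")
  list(sobs = length(k), f1 = sum(k == 1L), f2 = sum(k == 2L))
}

# Chao 1987 log-normal interval helper: T = chao1 - sobs.
.chao1CI <- function(sobs, chao1, variance, confLevel) {
  T <- chao1 - sobs
  if (T <= 0 || variance <= 0)
    return(c(low = as.numeric(sobs), high = as.numeric(sobs)))
  z <- stats::qnorm(1 - (1 - confLevel) / 2)
  K <- exp(z * sqrt(log(1 + variance / T^2)))
  c(low = sobs + T / K, high = sobs + T * K)
}

#' Chao1 nonparametric richness estimate
#'
#' Point estimate `Sobs + F1^2 / (2 F2)`, driven entirely by the singleton
#' and doubleton tallies. When `F2 = 0` the classical formula is undefined
#' and the bias-corrected term `F1 (F1 - 1) / (2 (F2 + 1))` is used instead
#' (flagged via the `biasCorrected` slot). The confidence interval is the
#' log-normal interval of Chao (1987): with `T = chao1 - Sobs` and
#' `K = exp(z * sqrt(log(1 + var/T^2)))`, bounds are `Sobs + T/K` and
#' `Sobs + T*K`; `T = 0` degenerates to `[Sobs, Sobs]`.
#'
#' @param a an [AbundanceVector-class].
#' @param confLevel nominal coverage of the interval (default 0.95).
#' @return A [RichnessEstimate-class].
#' @examples
#' a <- makeAbundances(sobs = 10, f1 = 4, f2 = 2, seed = 1)
#' chao1Estimate(a)
#' @references Chao, A. (1987) Estimating the population size for
#'   capture-recapture data with unequal catchability. Biometrics 43, 783-791.
#' @export
chao1Estimate <- function(a, confLevel = 0.95) {
  tf <- tallyFrequencies(a)
  sobs <- tf$sobs; f1 <- tf$f1; f2 <- tf$f2
  biasCorrected <- FALSE
  if (f2 > 0) {
    chao1 <- sobs + f1^2 / (2 * f2)
    G <- f1 / f2
    variance <- f2 * (G^2 / 2 + G^3 + G^4 / 4)
  } else if (f1 > 0) {
    biasCorrected <- TRUE
    chao1 <- sobs + f1 * (f1 - 1) / 2
    variance <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 -
      f1^4 / (4 * chao1)
  } else {
    chao1 <- as.numeric(sobs)
    variance <- 0
  }
  ci <- .chao1CI(sobs, chao1, variance, confLevel)
  new("RichnessEstimate", sobs = as.integer(sobs), f1 = as.integer(f1),
      f2 = as.integer(f2), chao1 = chao1, variance = variance,
      ciLow = unname(ci["low"]), ciHigh = unname(ci["high"]),
      confLevel = confLevel, biasCorrected = biasCorrected)
}

#' Randomized species-accumulation curve
#'
#' Individual fossil records are pooled in random order; observed richness
#' and Chao1 are recomputed at every accumulation level and averaged over
#' randomizations. Sampling is without replacement (a random permutation of
#' the records) by default; `replacement = TRUE` resamples records.
#'
#' @param a an [AbundanceVector-class].
#' @param nRand number of randomizations (>= 1).
#' @param replacement resample records with replacement?
#' @param seed optional RNG seed; a fixed seed makes the curve reproducible.
#' @param levels accumulation sizes; defaults to 1..N where N is the total
#'   record count. Levels beyond N are an error without replacement.
#' @return An [AccumulationCurve-class].
#' @examples
#' a <- makeAbundances(sobs = 12, f1 = 5, f2 = 3, seed = 1)
#' accumulationCurve(a, nRand = 50, seed = 1)
#' @export
accumulationCurve <- function(a, nRand = 1000, replacement = FALSE,
                              seed = NULL, levels = NULL) {
  stopifnot(is(a, "AbundanceVector"), nRand >= 1)
  k <- abundanceCounts(a)
  N <- sum(k)
  if (is.null(levels)) levels <- seq_len(N)
  levels <- sort(unique(as.integer(levels)))
  if (any(levels < 1)) stop("levels must be positive")
  if (!replacement && any(levels > N))
    stop("cannot accumulate beyond ", N, " records without replacement")
  pool <- rep.int(seq_along(k), k)
  maxLevel <- max(levels)
  withSeed(seed, {
    sumSobs <- numeric(length(levels))
    sumChao <- numeric(length(levels))
    for (r in seq_len(nRand)) {
      draw <- if (replacement) sample.int(N, maxLevel, replace = TRUE)
              else sample.int(N, maxLevel)
      ids <- pool[draw]
      cnt <- integer(length(k))
      sobs <- 0L; f1 <- 0L; f2 <- 0L
      li <- 1L
      for (step in seq_len(maxLevel)) {
        sp <- ids[step]
        cur <- cnt[sp] + 1L
        cnt[sp] <- cur
        if (cur == 1L) { sobs <- sobs + 1L; f1 <- f1 + 1L }
        else if (cur == 2L) { f1 <- f1 - 1L; f2 <- f2 + 1L }
        else if (cur == 3L) { f2 <- f2 - 1L }
        if (li <= length(levels) && step == levels[li]) {
          est <- if (f2 > 0) sobs + f1^2 / (2 * f2)
                 else if (f1 > 0) sobs + f1 * (f1 - 1) / 2
                 else as.numeric(sobs)
          sumSobs[li] <- sumSobs[li] + sobs
          sumChao[li] <- sumChao[li] + est
          li <- li + 1L
        }
      }
    }
    new("AccumulationCurve", levels = levels,
        meanSobs = sumSobs / nRand, meanChao1 = sumChao / nRand,
        nRand = as.integer(nRand),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        replacement = replacement)
  })
}

#' Plot an accumulation curve
#'
#' Mean observed richness (solid) and mean Chao1 (dashed) against the number
#' of pooled records.
#'
#' @param curve an [AccumulationCurve-class].
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the curve.
#' @export
plotAccumulationCurve <- function(curve, ...) {
  stopifnot(is(curve, "AccumulationCurve"))
  graphics::matplot(curve@levels, cbind(curve@meanSobs, curve@meanChao1),
                    type = "l", lty = c(1, 2), col = c("black", "grey40"),
                    xlab = "fossil records pooled",
                    ylab = "estimated species richness", ...)
  graphics::legend("bottomright", c("Sobs", "Chao1"), lty = c(1, 2),
                   col = c("black", "grey40"), bty = "n")
  invisible(curve)
}
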