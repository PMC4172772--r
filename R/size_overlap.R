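#' @include cooccurrence.R
NULL

# Transform, drop NAs (warning), enforce the >= 3 species minimum.
.preparedSizes <- function(sizes, transform) {
  v <- bodyLengths(sizes)
  if (anyNA(v)) {
    warning(sprintf("excluding %d species without size estimates",
                    sum(is.na(v))))
    v <- v[!is.na(v)]
  }
  if (length(v) < 3) stop("size-overlap analysis needs >= 3 sized species")
  if (transform == "log10") {
    if (any(v <= 0)) stop("log10 transform requires positive sizes")
    v <- log10(v)
  }
  v
}

.segmentMetrics <- function(sorted, varMethod) {
  seg <- unname(diff(sorted))
  varSeg <- if (varMethod == "population")
    mean((seg - mean(seg))^2) else stats::var(seg)
  list(segments = seg, varianceSegments = varSeg, minSegment = min(seg))
}

#' Segment-length profile of a body-size spectrum
#'
#' Sizes are transformed (log10 by default, matching the convention that
#' body-size spacing is judged on a ratio scale), sorted ascending and
#' differenced. The two size-overlap statistics are the variance of these
#' segments (low variance = evenly spaced sizes) and the minimum segment
#' (the gap between the closest pair of species).
#'
#' @param sizes a [BodySizeTable-class]; species without estimates are
#'   excluded with a warning; at least 3 sized species are required.
#' @param transform "log10" (default) or "identity".
#' @param varMethod "population" (divide by the segment count, default) or
#'   "sample" (divide by count - 1).
#' @return A [SizeSegmentProfile-class]. Tied sizes are permitted; the
#'   minimum segment is then 0 and a warning notes the tie.
#' @examples
#' segmentProfile(BodySizeTable(c("a", "b", "c"), c(1, 10, 100)))
#' @export
segmentProfile <- function(sizes, transform = c("log10", "identity"),
                           varMethod = c("population", "sample")) {
  stopifnot(is(sizes, "BodySizeTable"))
  transform <- match.arg(transform)
  varMethod <- match.arg(varMethod)
  v <- unname(sort(.preparedSizes(sizes, transform)))
  met <- .segmentMetrics(v, varMethod)
  if (met$minSegment == 0)
    warning("tied sizes: minimum segment length is 0")
  new("SizeSegmentProfile", sortedSizes = v, segments = met$segments,
      varianceSegments = met$varianceSegments, minSegment = met$minSegment,
      transform = transform)
}

#' Randomization test of body-size overlap
#'
#' Compares an observed segment-length statistic with pseudo-assemblages
#' drawn under a null model of unstructured sizes.
#'
#' With `mode = "uniform"` (default) the observed minimum and maximum
#' (transformed) sizes are retained as fixed endpoints and the n - 2
#' interior values are drawn independently and uniformly between them for
#' each pseudo-assemblage (the Barton-David-style segment null);
#' `fixedEndpoints = FALSE` draws all n values uniformly instead. With
#' `mode = "pool"` each pseudo-assemblage resamples n species from a
#' supplied source pool (without replacement, optionally weighted); the
#' pool must be strictly larger than the assemblage, otherwise every draw
#' is the assemblage itself and the null is degenerate.
#'
#' Structure is directional: an evenly packed ("structured") assemblage has
#' a variance of segments significantly *smaller* than null (`pLower`) and
#' a minimum segment significantly *greater* than null (`pUpper`). Both
#' tails are always reported, with the add-one correction and ties counted
#' toward the tail.
#'
#' @param sizes a [BodySizeTable-class] (>= 3 sized species).
#' @param metric "variance" (variance of segment lengths) or "min"
#'   (minimum segment length).
#' @param iterations number of pseudo-assemblages (default 10000).
#' @param mode "uniform" or "pool" (see Details).
#' @param transform "log10" (default) or "identity".
#' @param seed optional RNG seed.
#' @param fixedEndpoints keep the observed extremes fixed in uniform mode.
#' @param pool a [BodySizeTable-class] source pool (pool mode only).
#' @param poolWeights optional per-species colonization weights matching
#'   `pool`; equal weights when NULL.
#' @param varMethod variance convention, as in [segmentProfile()]; recorded
#'   in the statistic name.
#' @return A [NullModelResult-class].
#' @examples
#' sz <- makeSizes(10, pattern = "uniform", seed = 2)
#' nullModelSizeOverlap(sz, metric = "min", iterations = 500, seed = 1)
#' @export
nullModelSizeOverlap <- function(sizes, metric = c("variance", "min"),
                                 iterations = 10000,
                                 mode = c("uniform", "pool"),
                                 transform = c("log10", "identity"),
                                 seed = NULL, fixedEndpoints = TRUE,
                                 pool = NULL, poolWeights = NULL,
                                 varMethod = c("population", "sample")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  varMethod <- match.arg(varMethod)
  stopifnot(iterations >= 1)
  obs <- sort(.preparedSizes(sizes, transform))
  n <- length(obs)
  statOf <- function(sorted) {
    met <- .segmentMetrics(sorted, varMethod)
    if (metric == "variance") met$varianceSegments else met$minSegment
  }
  observed <- statOf(obs)

  nullValues <- withSeed(seed, {
    if (mode == "uniform") {
      a <- obs[1]; b <- obs[n]
      if (fixedEndpoints) {
        inner <- matrix(stats::runif((n - 2) * iterations, a, b), n - 2)
        draws <- rbind(a, inner, b)
      } else {
        draws <- matrix(stats::runif(n * iterations, a, b), n)
      }
      apply(draws, 2, function(x) statOf(sort(x)))
    } else {
      if (is.null(pool)) stop("pool mode requires a source pool")
      pv <- .preparedSizes(pool, transform)
      if (length(pv) <= n)
        stop("source pool must be larger than the assemblage; ",
             "an equal pool makes the null distribution constant")
      w <- if (is.null(poolWeights)) rep(1, length(pv)) else poolWeights
      if (length(w) != length(pv)) stop("poolWeights must match the pool")
      vapply(seq_len(iterations), function(i)
        statOf(sort(sample(pv, n, prob = w))), numeric(1))
    }
  })
  statName <- paste0(if (metric == "variance") "variance_segments"
                     else "min_segment",
                     "(", transform,
                     if (metric == "variance") paste0(",", varMethod) else "",
                     ")")
  .makeNullResult(statName, observed, nullValues, iterations,
                  burnIn = 0L, thin = 1L, seed = seed)
}
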