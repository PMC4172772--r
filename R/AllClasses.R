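#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# IncidenceMatrix

#' Binary species-by-site occurrence matrix
#'
#' The central container of the package: a presence (1) / absence (0) matrix
#' whose rows are species and whose columns are sites (here, stratigraphic
#' formations). All co-occurrence statistics consume this class.
#'
#' @slot occ integer matrix of 0/1 cells with unique, non-empty dimnames.
#'
#' @seealso [readIncidenceCsv()], [cScore()], [nullModelCscore()]
#' @export
setClass("IncidenceMatrix", representation(occ = "matrix"))

setValidity("IncidenceMatrix", function(object) {
  m <- object@occ
  msgs <- character()
  if (!is.numeric(m) && !is.integer(m))
    msgs <- c(msgs, "cells must be numeric 0/1")
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    msgs <- c(msgs, "every cell must be exactly 0 or 1")
  dn <- dimnames(m)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    msgs <- c(msgs, "species (row) and site (column) names are required")
  else {
    if (anyDuplicated(dn[[1]]))
      msgs <- c(msgs, sprintf("duplicate species name: '%s'",
                              dn[[1]][duplicated(dn[[1]])][1]))
    if (anyDuplicated(dn[[2]]))
      msgs <- c(msgs, sprintf("duplicate site name: '%s'",
                              dn[[2]][duplicated(dn[[2]])][1]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an IncidenceMatrix
#'
#' @param occ a 0/1 matrix with species as rownames and sites as colnames.
#' @return A validated [IncidenceMatrix-class].
#' @examples
#' m <- IncidenceMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("sp1", "sp2"), c("siteA", "siteB"))))
#' cScore(m)
#' @export
IncidenceMatrix <- function(occ) {
  storage.mode(occ) <- "integer"
  new("IncidenceMatrix", occ = occ)
}

#' Extract the raw occurrence matrix
#'
#' @param x an [IncidenceMatrix-class].
#' @return The underlying integer 0/1 matrix with dimnames.
#' @export
occurrenceMatrix <- function(x) {
  stopifnot(is(x, "IncidenceMatrix"))
  x@occ
}

#' @describeIn speciesNames row labels of the occurrence matrix
#' @export
setMethod("speciesNames", "IncidenceMatrix", function(x) rownames(x@occ))

#' @describeIn siteNames column labels of the occurrence matrix
#' @export
setMethod("siteNames", "IncidenceMatrix", function(x) colnames(x@occ))

#' @describeIn nSpecies number of rows of the occurrence matrix
#' @export
setMethod("nSpecies", "IncidenceMatrix", function(x) nrow(x@occ))

#' @describeIn nSites number of columns of the occurrence matrix
#' @export
setMethod("nSites", "IncidenceMatrix", function(x) ncol(x@occ))

setMethod("show", "IncidenceMatrix", function(object) {
  m <- object@occ
  cat(sprintf("IncidenceMatrix: %d species x %d sites, %d occurrences\n",
              nrow(m), ncol(m), sum(m)))
  cat("species:", paste(utils::head(rownames(m), 3), collapse = ", "),
      if (nrow(m) > 3) "..." else "", "\n")
  cat("sites:  ", paste(utils::head(colnames(m), 5), collapse = ", "),
      if (ncol(m) > 5) "..." else "", "\n")
})

# ---------------------------------------------------------------------------
# AbundanceVector

#' Per-species fossil-record counts
#'
#' Counts of individuals (fossil records) per species; the input to Chao1
#' estimation and accumulation curves. A species with zero records is not
#' part of the assemblage, so all counts are >= 1.
#'
#' @slot counts named integer vector of counts, one per species.
#' @export
setClass("AbundanceVector", representation(counts = "integer"))

setValidity("AbundanceVector", function(object) {
  k <- object@counts
  msgs <- character()
  if (length(k) == 0) msgs <- c(msgs, "empty abundance vector")
  if (anyNA(k) || any(k < 1L))
    msgs <- c(msgs, "counts must be integers >= 1")
  if (is.null(names(k)) || anyDuplicated(names(k)))
    msgs <- c(msgs, "species names must be present and unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AbundanceVector
#'
#' @param counts named vector of positive integer counts.
#' @return A validated [AbundanceVector-class].
#' @export
AbundanceVector <- function(counts) {
  k <- as.integer(round(counts))
  if (any(abs(counts - k) > 1e-8)) stop("counts must be whole numbers")
  names(k) <- names(counts)
  new("AbundanceVector", counts = k)
}

#' Extract the counts of an AbundanceVector
#'
#' @param x an [AbundanceVector-class].
#' @return Named integer vector.
#' @export
abundanceCounts <- function(x) {
  stopifnot(is(x, "AbundanceVector"))
  x@counts
}

#' @describeIn speciesNames names of the count vector
#' @export
setMethod("speciesNames", "AbundanceVector", function(x) names(x@counts))

#' @describeIn nSpecies length of the count vector
#' @export
setMethod("nSpecies", "AbundanceVector", function(x) length(x@counts))

setMethod("show", "AbundanceVector", function(object) {
  cat(sprintf("AbundanceVector: %d species, %d records\n",
              length(object@counts), sum(object@counts)))
})

# ---------------------------------------------------------------------------
# BodySizeTable

#' Per-species body lengths
#'
#' Estimated total body length per species, in meters. Missing estimates are
#' stored as NA and excluded (with a warning) from size-overlap analysis.
#'
#' @slot species character vector of unique species names.
#' @slot lengthM numeric lengths in meters; strictly positive where known,
#'   NA where the literature provides no estimate.
#' @export
setClass("BodySizeTable",
         representation(species = "character", lengthM = "numeric"))

setValidity("BodySizeTable", function(object) {
  msgs <- character()
  if (length(object@species) != length(object@lengthM))
    msgs <- c(msgs, "species and lengthM must have equal length")
  if (anyDuplicated(object@species))
    msgs <- c(msgs, "duplicate species names")
  bad <- !is.na(object@lengthM) & object@lengthM <= 0
  if (any(bad))
    msgs <- c(msgs, sprintf("non-positive length for '%s'",
                            object@species[bad][1]))
  if (length(msgs)) msgs else TRUE
})

#' Construct a BodySizeTable
#'
#' @param species character species names.
#' @param lengthM numeric body lengths in meters (NA allowed for unknown).
#' @return A validated [BodySizeTable-class].
#' @export
BodySizeTable <- function(species, lengthM) {
  new("BodySizeTable", species = as.character(species),
      lengthM = as.numeric(lengthM))
}

#' Extract body lengths (meters) from a BodySizeTable
#'
#' @param x a [BodySizeTable-class].
#' @param dropNA drop species without a length estimate.
#' @return Named numeric vector of lengths in meters.
#' @export
bodyLengths <- function(x, dropNA = FALSE) {
  stopifnot(is(x, "BodySizeTable"))
  v <- stats::setNames(x@lengthM, x@species)
  if (dropNA) v[!is.na(v)] else v
}

#' @describeIn speciesNames species column of the size table
#' @export
setMethod("speciesNames", "BodySizeTable", function(x) x@species)

#' @describeIn nSpecies number of rows of the size table
#' @export
setMethod("nSpecies", "BodySizeTable", function(x) length(x@species))

setMethod("show", "BodySizeTable", function(object) {
  known <- !is.na(object@lengthM)
  cat(sprintf("BodySizeTable: %d species (%d with length estimates)\n",
              length(object@species), sum(known)))
  if (any(known))
    cat(sprintf("range: %.1f - %.1f m\n",
                min(object@lengthM[known]), max(object@lengthM[known])))
})

# ---------------------------------------------------------------------------
# MarginProfile

#' Fixed margins of an incidence matrix
#'
#' Row totals (occupied sites per species) and column totals (species per
#' site); the quantities the fixed-fixed null model holds constant.
#'
#' @slot rowTotals named integer vector, one per species.
#' @slot colTotals named integer vector, one per site.
#' @export
setClass("MarginProfile",
         representation(rowTotals = "integer", colTotals = "integer"))

setValidity("MarginProfile", function(object) {
  if (sum(object@rowTotals) != sum(object@colTotals))
    "sum(rowTotals) must equal sum(colTotals)" else TRUE
})

#' Row totals of a MarginProfile
#' @param x a [MarginProfile-class].
#' @return Named integer vector.
#' @export
rowTotals <- function(x) { stopifnot(is(x, "MarginProfile")); x@rowTotals }

#' Column totals of a MarginProfile
#' @param x a [MarginProfile-class].
#' @return Named integer vector.
#' @export
colTotals <- function(x) { stopifnot(is(x, "MarginProfile")); x@colTotals }

setMethod("show", "MarginProfile", function(object) {
  cat(sprintf("MarginProfile: %d species / %d sites, %d occurrences\n",
              length(object@rowTotals), length(object@colTotals),
              sum(object@rowTotals)))
})

# ---------------------------------------------------------------------------
# RichnessEstimate

#' Chao1 richness estimate
#'
#' Observed richness, singleton/doubleton tallies, the Chao1 point estimate,
#' its estimator variance, and a log-normal confidence interval.
#'
#' @slot sobs observed species count.
#' @slot f1 singleton count (species with exactly one record).
#' @slot f2 doubleton count (species with exactly two records).
#' @slot chao1 point estimate (species).
#' @slot variance estimator variance.
#' @slot ciLow,ciHigh confidence bounds (species).
#' @slot confLevel nominal coverage of the interval.
#' @slot biasCorrected TRUE when the f2 = 0 fallback formula was used.
#' @export
setClass("RichnessEstimate",
         representation(sobs = "integer", f1 = "integer", f2 = "integer",
                        chao1 = "numeric", variance = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        confLevel = "numeric", biasCorrected = "logical"))

setValidity("RichnessEstimate", function(object) {
  msgs <- character()
  if (object@chao1 < object@sobs - 1e-9)
    msgs <- c(msgs, "chao1 must be >= sobs")
  if (object@ciLow < 0 || object@ciLow > object@chao1 + 1e-9 ||
      object@ciHigh < object@chao1 - 1e-9)
    msgs <- c(msgs, "confidence interval must contain the point estimate")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RichnessEstimate", function(object) {
  cat(sprintf("Chao1 richness estimate\n  Sobs = %d, F1 = %d, F2 = %d\n",
              object@sobs, object@f1, object@f2))
  cat(sprintf("  Chao1 = %.2f%s, %d%% CI [%.2f, %.2f]\n", object@chao1,
              if (object@biasCorrected) " (bias-corrected, F2 = 0)" else "",
              round(100 * object@confLevel), object@ciLow, object@ciHigh))
})

# ---------------------------------------------------------------------------
# AccumulationCurve

#' Randomized species-accumulation (rarefaction) curve
#'
#' Mean observed richness and mean Chao1 as individual fossil records are
#' pooled in random order, averaged over randomizations.
#'
#' @slot levels accumulation sizes (records pooled).
#' @slot meanSobs,meanChao1 averages over randomizations at each level.
#' @slot nRand number of randomizations.
#' @slot seed RNG seed used (NA when none was supplied).
#' @slot replacement TRUE when records were resampled with replacement.
#' @export
setClass("AccumulationCurve",
         representation(levels = "integer", meanSobs = "numeric",
                        meanChao1 = "numeric", nRand = "integer",
                        seed = "integer", replacement = "logical"))

setValidity("AccumulationCurve", function(object) {
  if (length(object@levels) != length(object@meanSobs) ||
      length(object@levels) != length(object@meanChao1))
    "levels, meanSobs and meanChao1 must align" else TRUE
})

setMethod("show", "AccumulationCurve", function(object) {
  cat(sprintf(
    "AccumulationCurve: %d levels, %d randomizations (%s replacement)\n",
    length(object@levels), object@nRand,
    if (object@replacement) "with" else "without"))
  cat(sprintf("  final mean Sobs = %.2f, mean Chao1 = %.2f\n",
              utils::tail(object@meanSobs, 1),
              utils::tail(object@meanChao1, 1)))
})

# ---------------------------------------------------------------------------
# NullModelResult

#' Observed statistic with its Monte Carlo null distribution
#'
#' Returned by all randomization tests in the package. Tail probabilities
#' use the add-one correction p = (1 + #{null at least as extreme}) /
#' (1 + iterations), with ties counted toward the tail.
#'
#' @slot statisticName label of the test statistic.
#' @slot observed observed value of the statistic.
#' @slot nullValues simulated statistic values (length = iterations).
#' @slot nullMean,nullSd summaries of the null distribution.
#' @slot ses standardized effect size (observed - nullMean)/nullSd; NA when
#'   nullSd = 0.
#' @slot pUpper,pLower upper and lower tail probabilities.
#' @slot iterations,burnIn,thin Monte Carlo controls used.
#' @slot seed RNG seed used (NA when none was supplied).
#' @slot degenerate TRUE when no randomization was possible (e.g. a
#'   perfectly nested matrix has no swappable submatrix).
#' @export
setClass("NullModelResult",
         representation(statisticName = "character", observed = "numeric",
                        nullValues = "numeric", nullMean = "numeric",
                        nullSd = "numeric", ses = "numeric",
                        pUpper = "numeric", pLower = "numeric",
                        iterations = "integer", burnIn = "integer",
                        thin = "integer", seed = "integer",
                        degenerate = "logical"))

setValidity("NullModelResult", function(object) {
  msgs <- character()
  if (length(object@nullValues) != object@iterations)
    msgs <- c(msgs, "length(nullValues) must equal iterations")
  p <- c(object@pUpper, object@pLower)
  if (any(p <= 0) || any(p > 1))
    msgs <- c(msgs, "tail probabilities must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Accessors for NullModelResult
#'
#' @param x a [NullModelResult-class].
#' @return `observedStat`: the observed statistic; `nullValues`: the vector
#'   of simulated values; `sesValue`: the standardized effect size;
#'   `pUpper`/`pLower`: tail probabilities.
#' @name nullmodel-accessors
NULL

#' @rdname nullmodel-accessors
#' @export
observedStat <- function(x) { stopifnot(is(x, "NullModelResult")); x@observed }

#' @rdname nullmodel-accessors
#' @export
nullValues <- function(x) { stopifnot(is(x, "NullModelResult")); x@nullValues }

#' @rdname nullmodel-accessors
#' @export
sesValue <- function(x) { stopifnot(is(x, "NullModelResult")); x@ses }

#' @rdname nullmodel-accessors
#' @export
pUpper <- function(x) { stopifnot(is(x, "NullModelResult")); x@pUpper }

#' @rdname nullmodel-accessors
#' @export
pLower <- function(x) { stopifnot(is(x, "NullModelResult")); x@pLower }

setMethod("show", "NullModelResult", function(object) {
  cat(sprintf("Null-model test of %s\n", object@statisticName))
  cat(sprintf("  observed = %.4f, null mean = %.4f (sd %.4f)\n",
              object@observed, object@nullMean, object@nullSd))
  cat(sprintf("  SES = %s, p(upper) = %.4g, p(lower) = %.4g\n",
              if (is.na(object@ses)) "NA" else sprintf("%.3f", object@ses),
              object@pUpper, object@pLower))
  cat(sprintf("  %d iterations (burn-in %d, thin %d)%s\n",
              object@iterations, object@burnIn, object@thin,
              if (object@degenerate) " [degenerate null]" else ""))
})

# ---------------------------------------------------------------------------
# SizeSegmentProfile

#' Segment-length profile of a body-size spectrum
#'
#' Sizes are transformed (log10 by default), sorted ascending, and
#' differenced; the n-1 consecutive differences ("segment lengths") carry
#' the spacing information the size-overlap tests examine.
#'
#' @slot sortedSizes transformed sizes, ascending.
#' @slot segments consecutive differences, length n-1.
#' @slot varianceSegments variance of the segments.
#' @slot minSegment smallest segment (distance between the closest pair).
#' @slot transform "log10" or "identity".
#' @export
setClass("SizeSegmentProfile",
         representation(sortedSizes = "numeric", segments = "numeric",
                        varianceSegments = "numeric", minSegment = "numeric",
                        transform = "character"))

setValidity("SizeSegmentProfile", function(object) {
  msgs <- character()
  if (length(object@segments) != length(object@sortedSizes) - 1)
    msgs <- c(msgs, "need length(segments) == n - 1")
  if (any(object@segments < -1e-12))
    msgs <- c(msgs, "segments must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SizeSegmentProfile", function(object) {
  cat(sprintf("SizeSegmentProfile (%s scale): %d species\n",
              object@transform, length(object@sortedSizes)))
  cat(sprintf("  variance of segments = %.5f, min segment = %.5f\n",
              object@varianceSegments, object@minSegment))
})

# ---------------------------------------------------------------------------
# AnalysisReport

setClassUnion("RichnessEstimateOrNULL", c("RichnessEstimate", "NULL"))
setClassUnion("AccumulationCurveOrNULL", c("AccumulationCurve", "NULL"))
setClassUnion("NullModelResultOrNULL", c("NullModelResult", "NULL"))

#' Full assemblage analysis report
#'
#' Bundles the richness, co-occurrence and size-overlap results of
#' [runAssemblageAnalysis()] with a provenance block (seeds, parameters,
#' input fingerprints, package version) sufficient to reproduce every
#' number exactly.
#'
#' @slot richness [RichnessEstimate-class] or NULL when no abundances were
#'   supplied.
#' @slot accumulation [AccumulationCurve-class] or NULL.
#' @slot cooccurrence C-score [NullModelResult-class].
#' @slot sizeOverlapVariance,sizeOverlapMin segment-length
#'   [NullModelResult-class] objects (NULL when too few sizes are known).
#' @slot provenance named list: seeds, parameter echo, input md5 digests,
#'   package version.
#' @slot notes character vector of machine-readable warnings/notices.
#' @export
setClass("AnalysisReport",
         representation(richness = "RichnessEstimateOrNULL",
                        accumulation = "AccumulationCurveOrNULL",
                        cooccurrence = "NullModelResultOrNULL",
                        sizeOverlapVariance = "NullModelResultOrNULL",
                        sizeOverlapMin = "NullModelResultOrNULL",
                        provenance = "list", notes = "character"))

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n==============\n")
  if (!is.null(object@richness)) show(object@richness)
  else cat("richness: skipped (no abundance data)\n")
  if (!is.null(object@cooccurrence)) show(object@cooccurrence)
  if (!is.null(object@sizeOverlapVariance)) show(object@sizeOverlapVariance)
  if (!is.null(object@sizeOverlapMin)) show(object@sizeOverlapMin)
  if (length(object@notes))
    cat("notes:\n", paste(" -", object@notes, collapse = "\n"), "\n")
  cat(sprintf("seed: %s, package version %s\n",
              object@provenance$seed, object@provenance$packageVersion))
})
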