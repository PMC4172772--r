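#' @include synthetic_data.R
NULL

#' Default analysis configuration
#'
#' Defaults mirror the study design the package ships as a fixture: 10,000
#' co-occurrence randomizations, 1,000 accumulation randomizations without
#' replacement, log10 size transform, 95% confidence level.
#'
#' @return Named list of defaults accepted by [runAssemblageAnalysis()].
#' @export
defaultAnalysisConfig <- function() {
  list(iterations = 10000, burnIn = 30000, thin = 1,
       accumulationRand = 1000, replacement = FALSE, confLevel = 0.95,
       transform = "log10", sizeMode = "uniform", varMethod = "population",
       dropEmpty = TRUE, seed = 1)
}

#' Run the full assemblage null-model analysis
#'
#' One call reproducing the whole pipeline on an incidence matrix, a
#' body-size table and (optionally) an abundance vector: Chao1 richness
#' with an accumulation curve, the fixed-fixed sequential-swap C-score
#' test, and both size-overlap tests (variance and minimum of log segment
#' lengths). All randomness flows from the single `seed` entry of the
#' configuration, fanned out deterministically to per-stage seeds, so the
#' provenance block of the report reproduces every number exactly.
#'
#' @param incidence an [IncidenceMatrix-class]; defaults to the packaged
#'   titanosaur matrix.
#' @param sizes a [BodySizeTable-class]; defaults to the packaged synthetic
#'   stand-in size table (see [titanosaurFixtures()]), since only two
#'   lengths of the original assemblage are pinned by the published record.
#' @param abundances an [AbundanceVector-class] or NULL; when NULL the
#'   richness stage is skipped with a logged notice.
#' @param config named list overriding entries of
#'   [defaultAnalysisConfig()]; an unknown key is an error before any
#'   computation starts.
#' @return An [AnalysisReport-class].
#' @examples
#' \donttest{
#' rep <- runAssemblageAnalysis(config = list(iterations = 500,
#'                                            burnIn = 5000, seed = 1))
#' rep
#' }
#' @export
runAssemblageAnalysis <- function(incidence = NULL, sizes = NULL,
                                  abundances = NULL, config = list()) {
  defaults <- defaultAnalysisConfig()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  notes <- character()

  if (is.null(incidence)) {
    incidence <- titanosaurFixtures()$incidence
    notes <- c(notes, "incidence: packaged titanosaur fixture")
  }
  if (is.null(sizes)) {
    sizes <- titanosaurFixtures(sizes = "synthetic")$sizes
    notes <- c(notes,
               "sizes: packaged synthetic stand-in table (two anchors only)")
  }
  stopifnot(is(incidence, "IncidenceMatrix"), is(sizes, "BodySizeTable"))

  richness <- NULL
  accumulation <- NULL
  if (is.null(abundances)) {
    notes <- c(notes, "richness: skipped, no abundance data supplied")
  } else {
    stopifnot(is(abundances, "AbundanceVector"))
    richness <- chao1Estimate(abundances, confLevel = cfg$confLevel)
    accumulation <- accumulationCurve(abundances,
                                      nRand = cfg$accumulationRand,
                                      replacement = cfg$replacement,
                                      seed = stageSeed(cfg$seed, 1))
  }

  coocc <- withCallingHandlers(
    nullModelCscore(incidence, iterations = cfg$iterations,
                    burnIn = cfg$burnIn, thin = cfg$thin,
                    seed = stageSeed(cfg$seed, 2),
                    dropEmpty = cfg$dropEmpty),
    warning = function(w) {
      notes <<- c(notes, paste("cooccurrence:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })

  runSize <- function(metric, stage) {
    withCallingHandlers(
      nullModelSizeOverlap(sizes, metric = metric,
                           iterations = cfg$iterations, mode = cfg$sizeMode,
                           transform = cfg$transform,
                           seed = stageSeed(cfg$seed, stage),
                           varMethod = cfg$varMethod),
      warning = function(w) {
        notes <<- c(notes, paste0("size_overlap(", metric, "): ",
                                  conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  nSized <- sum(!is.na(bodyLengths(sizes)))
  if (nSized >= 3) {
    sizeVar <- runSize("variance", 3)
    sizeMin <- runSize("min", 4)
  } else {
    sizeVar <- NULL
    sizeMin <- NULL
    notes <- c(notes, sprintf(
      "size_overlap: skipped, only %d species have size estimates", nSized))
  }

  prov <- list(
    seed = cfg$seed,
    stageSeeds = list(accumulation = stageSeed(cfg$seed, 1),
                      cooccurrence = stageSeed(cfg$seed, 2),
                      sizeVariance = stageSeed(cfg$seed, 3),
                      sizeMin = stageSeed(cfg$seed, 4)),
    config = cfg,
    inputDigests = list(
      incidence = .fingerprint(c(
        paste(speciesNames(incidence), collapse = "|"),
        paste(siteNames(incidence), collapse = "|"),
        paste(as.vector(occurrenceMatrix(incidence)), collapse = ""))),
      sizes = .fingerprint(paste(speciesNames(sizes),
                                 bodyLengths(sizes), sep = ":")),
      abundances = if (is.null(abundances)) NA_character_ else
        .fingerprint(paste(speciesNames(abundances),
                           abundanceCounts(abundances), sep = ":"))),
    packageVersion = as.character(utils::packageVersion("assemblageNull")))

  new("AnalysisReport", richness = richness, accumulation = accumulation,
      cooccurrence = coocc, sizeOverlapVariance = sizeVar,
      sizeOverlapMin = sizeMin, provenance = prov, notes = notes)
}

.nullResultAsList <- function(x, keepNull = FALSE) {
  if (is.null(x)) return(NULL)
  out <- list(statistic = x@statisticName, observed = x@observed,
              nullMean = x@nullMean, nullSd = x@nullSd, ses = x@ses,
              pUpper = x@pUpper, pLower = x@pLower,
              iterations = x@iterations, burnIn = x@burnIn, thin = x@thin,
              seed = x@seed, degenerate = x@degenerate)
  if (keepNull) out$nullValues <- x@nullValues
  out
}

#' Serialize an AnalysisReport to JSON
#'
#' Writes the numeric report (observed statistics, null summaries, tail
#' probabilities, provenance) as structured JSON; the canonical output of
#' the pipeline — plots are optional artifacts.
#'
#' @param report an [AnalysisReport-class].
#' @param path output file path.
#' @param keepNullValues include the full null distributions (large).
#' @return `path`, invisibly.
#' @export
writeAnalysisReport <- function(report, path, keepNullValues = FALSE) {
  stopifnot(is(report, "AnalysisReport"))
  rich <- if (is.null(report@richness)) NULL else list(
    sobs = report@richness@sobs, f1 = report@richness@f1,
    f2 = report@richness@f2, chao1 = report@richness@chao1,
    variance = report@richness@variance, ciLow = report@richness@ciLow,
    ciHigh = report@richness@ciHigh,
    confLevel = report@richness@confLevel,
    biasCorrected = report@richness@biasCorrected)
  out <- list(
    richness = rich,
    cooccurrence = .nullResultAsList(report@cooccurrence, keepNullValues),
    sizeOverlapVariance = .nullResultAsList(report@sizeOverlapVariance,
                                            keepNullValues),
    sizeOverlapMin = .nullResultAsList(report@sizeOverlapMin,
                                       keepNullValues),
    notes = report@notes,
    provenance = report@provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
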