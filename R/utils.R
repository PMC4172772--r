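#' @include AllClasses.R
NULL

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (is.na(seed) || seed != as.integer(seed)))
    stop("seed must be a single integer")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Add-one (include-observed) tail probabilities; ties count toward the tail.
.tailProbs <- function(observed, nullValues, tol = 1e-12) {
  n <- length(nullValues)
  list(pUpper = (1 + sum(nullValues >= observed - tol)) / (1 + n),
       pLower = (1 + sum(nullValues <= observed + tol)) / (1 + n))
}

# Assemble a NullModelResult from an observed value and simulated draws.
.makeNullResult <- function(statisticName, observed, nullValues,
                            iterations, burnIn, thin, seed,
                            degenerate = FALSE) {
  nullMean <- mean(nullValues)
  nullSd <- stats::sd(nullValues)
  if (is.na(nullSd)) nullSd <- 0
  ses <- if (nullSd > 0) (observed - nullMean) / nullSd else NA_real_
  pr <- .tailProbs(observed, nullValues)
  new("NullModelResult", statisticName = statisticName,
      observed = observed, nullValues = as.numeric(nullValues),
      nullMean = nullMean, nullSd = nullSd, ses = ses,
      pUpper = pr$pUpper, pLower = pr$pLower,
      iterations = as.integer(iterations), burnIn = as.integer(burnIn),
      thin = as.integer(thin),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      degenerate = degenerate)
}

# Derive a per-stage seed from a top-level seed (kept below 2^31).
stageSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483647)
}

# md5 fingerprint of an in-memory object via its canonical text serialization
.fingerprint <- function(lines) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}
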