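#' @include utils.R
NULL

#' Read a presence/absence matrix from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row of site names and
#' a first column of species names. Cells must be exactly "0" or "1" after
#' whitespace stripping; anything else (including "2" or blanks) is a parse
#' error naming the offending row and column — silent coercion would mask
#' transcription errors in hand-entered occurrence tables.
#'
#' @param path path to the CSV file.
#' @param sep field separator, "," by default.
#' @return A validated [IncidenceMatrix-class]; row and column order are
#'   preserved from the file. All-zero rows or columns are permitted here
#'   (with a warning); co-occurrence functions drop them by default.
#' @examples
#' f <- system.file("extdata", "titanosaur_incidence.csv",
#'                  package = "assemblageNull")
#' m <- readIncidenceCsv(f)
#' nSpecies(m)
#' @export
readIncidenceCsv <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, sep = sep,
                         check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("need a species column plus at least one site")
  species <- trimws(raw[[1]])
  sites <- colnames(raw)[-1]
  if (anyDuplicated(species))
    stop(sprintf("duplicate species label: '%s'",
                 species[duplicated(species)][1]))
  if (anyDuplicated(sites))
    stop(sprintf("duplicate site label: '%s'", sites[duplicated(sites)][1]))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[] <- trimws(cells)
  bad <- which(matrix(!(cells %in% c("0", "1")), nrow = nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "non-binary cell '%s' at species '%s', site '%s'",
      cells[bad[1, 1], bad[1, 2]], species[bad[1, 1]], sites[bad[1, 2]]))
  m <- matrix(as.integer(cells), nrow = length(species),
              dimnames = list(species, sites))
  if (any(rowSums(m) == 0))
    warning("matrix contains all-zero species rows")
  if (any(colSums(m) == 0))
    warning("matrix contains all-zero site columns")
  IncidenceMatrix(m)
}

#' Write an IncidenceMatrix to CSV
#'
#' Inverse of [readIncidenceCsv()]: a round trip reproduces cells and labels
#' exactly.
#'
#' @param m an [IncidenceMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIncidenceCsv <- function(m, path) {
  stopifnot(is(m, "IncidenceMatrix"))
  df <- data.frame(species = speciesNames(m), occurrenceMatrix(m),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column species,value CSV
#'
#' @param path path to a CSV with columns species,value (header required;
#'   the value column name is free, e.g. `length_m` or `count`).
#' @return data.frame with columns `species` (character) and `value`
#'   (numeric, NA allowed).
#' @keywords internal
.readSpeciesValueCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) != 2) stop("expected exactly two columns (species,value)")
  species <- trimws(raw[[1]])
  if (anyDuplicated(species))
    stop(sprintf("duplicate species label: '%s'",
                 species[duplicated(species)][1]))
  val <- suppressWarnings(as.numeric(trimws(raw[[2]])))
  bad <- !is.na(trimws(raw[[2]])) & trimws(raw[[2]]) != "NA" & is.na(val)
  if (any(bad))
    stop(sprintf("non-numeric value '%s' for species '%s'",
                 raw[[2]][bad][1], species[bad][1]))
  data.frame(species = species, value = val, stringsAsFactors = FALSE)
}

#' Read a body-size table from CSV
#'
#' @param path two-column CSV (species, length in meters; NA for species
#'   without a published estimate).
#' @return A [BodySizeTable-class].
#' @export
readBodySizeCsv <- function(path) {
  df <- .readSpeciesValueCsv(path)
  BodySizeTable(df$species, df$value)
}

#' Read an abundance vector from CSV
#'
#' @param path two-column CSV (species, positive integer record count).
#' @return An [AbundanceVector-class].
#' @export
readAbundanceCsv <- function(path) {
  df <- .readSpeciesValueCsv(path)
  if (anyNA(df$value)) stop("abundance counts cannot be NA")
  AbundanceVector(stats::setNames(df$value, df$species))
}

#' Packaged titanosaur fixtures
#'
#' Returns the Late Cretaceous South American titanosaur occurrence matrix
#' (23 species across 14 stratigraphic formations, 33 occurrences) together
#' with a per-species body-length table.
#'
#' Only two body lengths are pinned by the published record available here:
#' *Rocasaurus muniozi* (8 m) and *Puertasaurus reuili* (30 m). With
#' `sizes = "recorded"` (default) the remaining 21 species carry NA rather
#' than invented numbers. With `sizes = "synthetic"` a complete stand-in
#' table is returned: the two anchors plus 21 log-uniform draws strictly
#' between them, generated once under a fixed seed and shipped as
#' `titanosaur_sizes_synthetic.csv`. The synthetic table supports end-to-end
#' size-overlap runs but carries no per-species information beyond the
#' anchors; treat its per-species values as placeholders.
#'
#' @param sizes "recorded" or "synthetic" (see Details).
#' @return A list with elements `incidence` ([IncidenceMatrix-class]) and
#'   `sizes` ([BodySizeTable-class]). A cross-fixture consistency check
#'   (exact binomial-name matching) runs at load.
#' @examples
#' fx <- titanosaurFixtures()
#' margins(fx$incidence)
#' @export
titanosaurFixtures <- function(sizes = c("recorded", "synthetic")) {
  sizes <- match.arg(sizes)
  inc <- readIncidenceCsv(system.file("extdata", "titanosaur_incidence.csv",
                                      package = "assemblageNull"))
  sizeFile <- if (sizes == "recorded") "titanosaur_sizes.csv"
              else "titanosaur_sizes_synthetic.csv"
  bst <- readBodySizeCsv(system.file("extdata", sizeFile,
                                     package = "assemblageNull"))
  if (!identical(sort(speciesNames(inc)), sort(speciesNames(bst))))
    stop("fixture species names disagree between incidence and size tables")
  list(incidence = inc, sizes = bst)
}

#' @describeIn margins row/column totals of the occurrence matrix
#' @export
setMethod("margins", "IncidenceMatrix", function(m) {
  occ <- occurrenceMatrix(m)
  new("MarginProfile",
      rowTotals = stats::setNames(as.integer(rowSums(occ)), rownames(occ)),
      colTotals = stats::setNames(as.integer(colSums(occ)), colnames(occ)))
})
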