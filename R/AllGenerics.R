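#' @include RcppExports.R
NULL

#' Species labels of an assemblage object
#'
#' @param x an [IncidenceMatrix-class], [AbundanceVector-class] or
#'   [BodySizeTable-class] object.
#' @return Character vector of species names, in storage order.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' Site (formation) labels of an incidence matrix
#'
#' @param x an [IncidenceMatrix-class].
#' @return Character vector of site names.
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))

#' Number of species in an assemblage object
#'
#' @param x a domain object carrying species.
#' @return Integer count.
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' Number of sites in an incidence matrix
#'
#' @param x an [IncidenceMatrix-class].
#' @return Integer count.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' Row and column totals of an incidence matrix
#'
#' Row totals count the sites occupied by each species; column totals count
#' the species recorded at each site. Both margins are held fixed by the
#' sequential-swap null model.
#'
#' @param m an [IncidenceMatrix-class].
#' @return A [MarginProfile-class].
#' @export
setGeneric("margins", function(m) standardGeneric("margins"))

#' C-score of an incidence matrix
#'
#' Mean number of checkerboard units over all unordered species pairs; see
#' [checkerboardUnits()]. High values indicate spatial segregation.
#'
#' @param m an [IncidenceMatrix-class] with at least two species.
#' @param dropEmpty drop all-zero rows/columns (with a warning) before
#'   computing; an absent species contributes only degenerate pairs.
#' @return A single numeric value.
#' @export
setGeneric("cScore", function(m, dropEmpty = TRUE) standardGeneric("cScore"))

#' Number of species pairs forming at least one checkerboard unit
#'
#' @inheritParams cScore
#' @return Integer count of unordered pairs with CU > 0.
#' @export
setGeneric("checkerboardPairCount",
           function(m, dropEmpty = TRUE) standardGeneric("checkerboardPairCount"))
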