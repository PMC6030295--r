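#' @include units.R
NULL

#' Accessors for migration-network objects
#'
#' `nodes()` and `links()` return the node and link tables of a
#' [MigrationNetwork-class] object; `nNodes()`, `nLinks()` and
#' `nSeasons()` return the corresponding counts, and `seasonWidth()`
#' the width \eqn{\Delta\tau = T/m} of one seasonal interval in radians.
#'
#' @param x a [MigrationNetwork-class] object.
#' @return `nodes()` and `links()` return data frames; the others return
#'   single numbers.
#' @aliases nodes links nNodes nLinks nSeasons seasonWidth
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname network-accessors
#' @export
setGeneric("links", function(x) standardGeneric("links"))

#' @rdname network-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname network-accessors
#' @export
setGeneric("nLinks", function(x) standardGeneric("nLinks"))

#' @rdname network-accessors
#' @export
setGeneric("nSeasons", function(x) standardGeneric("nSeasons"))

#' @rdname network-accessors
#' @export
setGeneric("seasonWidth", function(x) standardGeneric("seasonWidth"))

#' Extract density values
#'
#' @param x a [DensityField-class] object.
#' @return the underlying `m x n` numeric matrix (seasons in rows,
#'   nodes in columns), with small negative numerical noise clipped
#'   to 0.
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
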