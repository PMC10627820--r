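#' Accessor generics
#'
#' Small accessor generics shared by the container classes: `heights()`
#' returns a height grid in metres, `validMask()` a logical grid of usable
#' pixels, `geoRef()` the grid georeference, `predMean()`/`predSd()` the fused
#' prediction bands, `nDates()` the number of acquisitions in a stack and
#' `ensembleSize()` the number of ensemble members.
#'
#' @param x an object of one of the canopyfuse container classes.
#' @return The slot value; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("geoRef", function(x) standardGeneric("geoRef"))

#' @rdname accessors
#' @export
setGeneric("predMean", function(x) standardGeneric("predMean"))

#' @rdname accessors
#' @export
setGeneric("predSd", function(x) standardGeneric("predSd"))

#' @rdname accessors
#' @export
setGeneric("nDates", function(x) standardGeneric("nDates"))

#' @rdname accessors
#' @export
setGeneric("ensembleSize", function(x) standardGeneric("ensembleSize"))
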