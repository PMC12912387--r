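#' Accessors for SalivaClock containers
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x a SalivaClock S4 object.
#' @param object a [HarmonicFit-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ctData", function(x) standardGeneric("ctData"))
#' @rdname accessors
#' @export
setMethod("ctData", "CtTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("seriesPoints", function(x) standardGeneric("seriesPoints"))
#' @rdname accessors
#' @export
setMethod("seriesPoints", "ExpressionSeriesSet", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))
#' @rdname accessors
#' @export
setMethod("exclusionLog", "ExpressionSeriesSet", function(x) x@log)

#' @rdname accessors
#' @export
setGeneric("hormoneSamples", function(x) standardGeneric("hormoneSamples"))
#' @rdname accessors
#' @export
setMethod("hormoneSamples", "HormoneSeries", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("analyte", function(x) standardGeneric("analyte"))
#' @rdname accessors
#' @export
setMethod("analyte", "HormoneSeries", function(x) x@analyte)

#' @rdname accessors
#' @export
setGeneric("participant", function(x) standardGeneric("participant"))
#' @rdname accessors
#' @export
setMethod("participant", "HormoneSeries", function(x) x@participant)

#' @rdname accessors
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setMethod("cellCounts", "CellCountTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("mesor", function(object) standardGeneric("mesor"))
#' @rdname accessors
#' @export
setMethod("mesor", "HarmonicFit", function(object) object@mu)

#' @rdname accessors
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setMethod("amplitude", "HarmonicFit", function(object) object@amplitude)

#' @rdname accessors
#' @export
setGeneric("acrophase", function(object) standardGeneric("acrophase"))
#' @rdname accessors
#' @export
setMethod("acrophase", "HarmonicFit", function(object) object@acrophase_h)

#' @rdname accessors
#' @export
setGeneric("isSaturated", function(object) standardGeneric("isSaturated"))
#' @rdname accessors
#' @export
setMethod("isSaturated", "HarmonicFit", function(object) object@saturated)

#' Coerce containers to data.frame
#' @param x object to coerce.
#' @param row.names,optional,... passed through (unused).
#' @return data.frame view of the container.
#' @export
as.data.frame.CtTable <- function(x, row.names = NULL, optional = FALSE, ...) x@data
#' @rdname as.data.frame.CtTable
#' @export
as.data.frame.ExpressionSeriesSet <- function(x, row.names = NULL, optional = FALSE, ...) x@points
#' @rdname as.data.frame.CtTable
#' @export
as.data.frame.CellCountTable <- function(x, row.names = NULL, optional = FALSE, ...) x@data
#' @rdname as.data.frame.CtTable
#' @export
as.data.frame.HormoneSeries <- function(x, row.names = NULL, optional = FALSE, ...) {
  cbind(participant = x@participant, analyte = x@analyte, x@samples)
}

setMethod("as.data.frame", "CtTable", as.data.frame.CtTable)
setMethod("as.data.frame", "ExpressionSeriesSet", as.data.frame.ExpressionSeriesSet)
setMethod("as.data.frame", "CellCountTable", as.data.frame.CellCountTable)
setMethod("as.data.frame", "HormoneSeries", as.data.frame.HormoneSeries)

#' @rdname accessors
#' @export
setGeneric("fitHarmonic", function(x, ...) standardGeneric("fitHarmonic"))

#' @rdname accessors
#' @export
setGeneric("fitHarmonicRobust", function(x, ...) standardGeneric("fitHarmonicRobust"))
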