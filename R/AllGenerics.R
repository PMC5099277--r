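#' Accessors
#'
#' Accessor generics for the package's S4 containers. Use these instead of
#' reaching into slots.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x, ...) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x, ...) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("caTrace", function(x, ...) standardGeneric("caTrace"))

#' @rdname accessors
#' @export
setGeneric("stepTable", function(x, ...) standardGeneric("stepTable"))

#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x, ...) standardGeneric("segmentTable"))

#' @rdname accessors
#' @export
setGeneric("pertClass", function(x, ...) standardGeneric("pertClass"))

#' @rdname accessors
#' @export
setGeneric("maxbaSeq", function(x, ...) standardGeneric("maxbaSeq"))

#' @rdname accessors
#' @export
setGeneric("maxbaValue", function(x, ...) standardGeneric("maxbaValue"))

#' @rdname accessors
#' @export
setGeneric("prolineSeq", function(x, ...) standardGeneric("prolineSeq"))

#' Per-step series accessors and computations
#'
#' @param x A \linkS4class{HelixSteps} object (or coordinates, see methods).
#' @param ... Passed to methods.
#' @name steps-api
NULL

#' @rdname steps-api
#' @export
setGeneric("stepSeries", function(x, ...) standardGeneric("stepSeries"))

#' @rdname steps-api
#' @export
setGeneric("insertKink", function(x, ...) standardGeneric("insertKink"))
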