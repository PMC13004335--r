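#' @rdname InteractionTable-class
#' @param x An object.
#' @export
setGeneric("interactionData", function(x) standardGeneric("interactionData"))

#' @rdname InteractionTable-class
#' @export
setGeneric("stateLabel", function(x) standardGeneric("stateLabel"))

#' @rdname StateSet-class
#' @param x An object.
#' @export
setGeneric("stateIndex", function(x) standardGeneric("stateIndex"))

#' @rdname StateSet-class
#' @export
setGeneric("lrSets", function(x) standardGeneric("lrSets"))

#' @rdname StateSet-class
#' @export
setGeneric("commTypes", function(x) standardGeneric("commTypes"))

#' @rdname CCCComparison-class
#' @param x An object.
#' @export
setGeneric("seTable", function(x) standardGeneric("seTable"))

#' @rdname CCCComparison-class
#' @export
setGeneric("classificationTable",
           function(x) standardGeneric("classificationTable"))

#' Aggregate per-type SE scores to an organ-level summary
#'
#' @param x A [CCCComparison] or the per-type SE `data.frame` from
#'   [seTable()].
#' @param ... Passed to methods; see [aggregateOrgan,data.frame-method].
#' @export
setGeneric("aggregateOrgan", function(x, ...) standardGeneric("aggregateOrgan"))
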