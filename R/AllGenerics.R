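#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics for the S4 classes in this package. Slot access by
#' `@` is discouraged; use these instead.
#'
#' @param x An object.
#' @param ... Further arguments for methods.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @rdname accessors
#' @export
setGeneric("geneSide", function(x) standardGeneric("geneSide"))

#' @rdname accessors
#' @export
setGeneric("geneSeq", function(x) standardGeneric("geneSeq"))

#' @rdname accessors
#' @export
setGeneric("extendedSeq", function(x) standardGeneric("extendedSeq"))

#' @rdname accessors
#' @export
setGeneric("scenarios", function(x) standardGeneric("scenarios"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("productivity", function(x) standardGeneric("productivity"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("scenarioProbs", function(x) standardGeneric("scenarioProbs"))

#' @rdname accessors
#' @export
setGeneric("nIterations", function(x) standardGeneric("nIterations"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' @rdname accessors
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))
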