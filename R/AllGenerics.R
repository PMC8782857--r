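#' @name geneDecay-accessors
#' @title Accessors for geneDecay classes
#'
#' @description Small accessor generics for the package's S4 classes; use
#' these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @return The slot value (see each method).
NULL

#' @rdname geneDecay-accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("lengthAa", function(x) standardGeneric("lengthAa"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("startOffset", function(x) standardGeneric("startOffset"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("stopFound", function(x) standardGeneric("stopFound"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("stopOffset", function(x) standardGeneric("stopOffset"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("alignedRef", function(x) standardGeneric("alignedRef"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("alignedQuery", function(x) standardGeneric("alignedQuery"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("statusCall", function(x) standardGeneric("statusCall"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("predictedFraction", function(x) standardGeneric("predictedFraction"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("matchSegments", function(x) standardGeneric("matchSegments"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("unitLength", function(x) standardGeneric("unitLength"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("eventCount", function(x) standardGeneric("eventCount"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("nodeStates", function(x) standardGeneric("nodeStates"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("isAmbiguous", function(x) standardGeneric("isAmbiguous"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname geneDecay-accessors
#' @export
setGeneric("speciesTree", function(x) standardGeneric("speciesTree"))
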