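#' @rdname signatureProbes
#' @export
setGeneric("signatureProbes", function(object, ...) standardGeneric("signatureProbes"))

#' @rdname filterTrail
#' @export
setGeneric("filterTrail", function(object) standardGeneric("filterTrail"))

#' @rdname signatureTable
#' @export
setGeneric("signatureTable", function(object, ...) standardGeneric("signatureTable"))

#' @rdname voteCounts
#' @export
setGeneric("voteCounts", function(object) standardGeneric("voteCounts"))

#' @rdname assignments
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname survivingProbes
#' @export
setGeneric("survivingProbes", function(object) standardGeneric("survivingProbes"))
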