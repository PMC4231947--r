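#' @rdname OTAlignment-class
#' @param x,object An object.
#' @param ... Further arguments (unused).
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname OTAlignment-class
#' @export
setGeneric("alignmentLength",
    function(x) standardGeneric("alignmentLength"))

#' @rdname OTAlignment-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname OTAlignment-class
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' @rdname OTTable-class
#' @param x,object An object.
#' @export
setGeneric("otLabels", function(x) standardGeneric("otLabels"))

#' @rdname OTTable-class
#' @export
setGeneric("otCounts", function(x) standardGeneric("otCounts"))

#' @rdname OTTable-class
#' @export
setGeneric("otTotals", function(x) standardGeneric("otTotals"))

#' @rdname OTAssignment-class
#' @param x,object An object.
#' @export
setGeneric("otAssignments", function(x) standardGeneric("otAssignments"))
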