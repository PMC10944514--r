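#' @rdname TranscriptAnnotation-class
#' @param x A `TranscriptAnnotation`.
#' @export
setGeneric("transcriptModels", function(x) standardGeneric("transcriptModels"))

#' @rdname TranscriptAnnotation-class
#' @export
setGeneric("refJunctions", function(x) standardGeneric("refJunctions"))

#' @rdname TranscriptAnnotation-class
#' @export
setGeneric("geneFootprints", function(x) standardGeneric("geneFootprints"))

#' @rdname JunctionCatalog-class
#' @param x A `JunctionCatalog`.
#' @export
setGeneric("junctionKeys", function(x) standardGeneric("junctionKeys"))

#' @rdname JunctionCatalog-class
#' @export
setGeneric("isAnnotated", function(x) standardGeneric("isAnnotated"))

#' @rdname JunctionCatalog-class
#' @export
setGeneric("hostGene", function(x) standardGeneric("hostGene"))

#' @rdname PositivityCalls-class
#' @param x A `PositivityCalls`.
#' @export
setGeneric("isPositive", function(x) standardGeneric("isPositive"))

#' @rdname ScreenResult-class
#' @param x A `ScreenResult`.
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname ScreenResult-class
#' @export
setGeneric("screenLedger", function(x) standardGeneric("screenLedger"))

#' @rdname ScreenResult-class
#' @export
setGeneric("consequenceReports", function(x) standardGeneric("consequenceReports"))

#' @rdname ScreenResult-class
#' @export
setGeneric("finalCandidates", function(x) standardGeneric("finalCandidates"))
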