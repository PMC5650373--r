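#' @rdname fpkm
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @rdname fpkm
#' @export
setGeneric("log2fpkm", function(x) standardGeneric("log2fpkm"))

#' @rdname sampleCondition
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))

#' @rdname sampleCondition
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname sampleCondition
#' @export
setGeneric("stageClass", function(x) standardGeneric("stageClass"))

#' @rdname geneSets
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname networkNodes
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkNodes
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @rdname networkNodes
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))
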