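#' @rdname CapturePanel-class
#' @param x a \code{CapturePanel} (or other object with genotypes).
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname CapturePanel-class
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname CapturePanel-class
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname CapturePanel-class
#' @export
setGeneric("genomeIndex", function(x) standardGeneric("genomeIndex"))

#' @rdname CapturePanel-class
#' @export
setGeneric("alignmentStats", function(x) standardGeneric("alignmentStats"))

#' @rdname CaptureMetrics-class
#' @param x a \code{CaptureMetrics}.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname CnvCallSet-class
#' @param x a \code{CnvCallSet}.
#' @export
setGeneric("cnvCalls", function(x) standardGeneric("cnvCalls"))

#' @rdname CaptureSimulation-class
#' @param x a \code{CaptureSimulation}.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname CaptureSimulation-class
#' @export
setGeneric("panel", function(x) standardGeneric("panel"))
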