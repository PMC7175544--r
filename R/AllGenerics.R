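#' @rdname BinGrid-class
#' @param x,object A package object.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname BinGrid-class
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' @rdname BinGrid-class
#' @export
setGeneric("binWeights", function(x) standardGeneric("binWeights"))

#' @rdname BinGrid-class
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname CopyNumberProfile-class
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname CopyNumberProfile-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SegmentSet-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname CutoffCalibration-class
#' @export
setGeneric("cutoff", function(x) standardGeneric("cutoff"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
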