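#' @import methods
NULL

#' @export
setGeneric("pixelSizeNm", function(x) standardGeneric("pixelSizeNm"))

#' @export
setGeneric("frameIntervalS", function(x) standardGeneric("frameIntervalS"))

#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))

#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @export
setGeneric("getChannel", function(x, label) standardGeneric("getChannel"))

#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @export
setGeneric("regionDiameter", function(region, calibration) standardGeneric("regionDiameter"))

#' @export
setGeneric("timesS", function(x) standardGeneric("timesS"))

#' @export
setGeneric("areasUm2", function(x) standardGeneric("areasUm2"))

#' @export
setGeneric("smoothedAreasUm2", function(x) standardGeneric("smoothedAreasUm2"))

#' @export
setGeneric("isContracting", function(x) standardGeneric("isContracting"))

#' @export
setGeneric("onsetS", function(x) standardGeneric("onsetS"))

#' @export
setGeneric("tMaxSpreadS", function(x) standardGeneric("tMaxSpreadS"))

#' @export
setGeneric("maxAreaUm2", function(x) standardGeneric("maxAreaUm2"))

#' @export
setGeneric("kymoSamples", function(x) standardGeneric("kymoSamples"))

#' @export
setGeneric("sampleRadiiUm", function(x) standardGeneric("sampleRadiiUm"))

#' @export
setGeneric("angleDeg", function(x) standardGeneric("angleDeg"))

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
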