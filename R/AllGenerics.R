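#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname accessors
#' @export
setGeneric("nEchoes", function(x) standardGeneric("nEchoes"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nNoiseFrames", function(x) standardGeneric("nNoiseFrames"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("magnitudeData", function(x, echo) standardGeneric("magnitudeData"))

#' @rdname accessors
#' @export
setGeneric("phaseData", function(x, echo) standardGeneric("phaseData"))

#' @rdname accessors
#' @export
setGeneric("hasPhase", function(x) standardGeneric("hasPhase"))

#' @rdname accessors
#' @export
setGeneric("t2starValues", function(x) standardGeneric("t2starValues"))

#' @rdname accessors
#' @export
setGeneric("r2starValues", function(x) standardGeneric("r2starValues"))

#' @rdname accessors
#' @export
setGeneric("s0Values", function(x) standardGeneric("s0Values"))

#' @rdname accessors
#' @export
setGeneric("validVoxels", function(x) standardGeneric("validVoxels"))

#' @rdname accessors
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

#' @rdname accessors
#' @export
setGeneric("fdSeries", function(x) standardGeneric("fdSeries"))

#' @rdname accessors
#' @export
setGeneric("retainedFrames", function(x) standardGeneric("retainedFrames"))

#' @rdname accessors
#' @export
setGeneric("pctRetained", function(x) standardGeneric("pctRetained"))

#' @rdname accessors
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))

#' @rdname accessors
#' @export
setGeneric("nodeKind", function(x) standardGeneric("nodeKind"))

#' @rdname accessors
#' @export
setGeneric("tsnrValues", function(x) standardGeneric("tsnrValues"))

#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))

#' @rdname accessors
#' @export
setGeneric("noiseSource", function(x) standardGeneric("noiseSource"))

#' Extract one echo from a multi-echo series
#'
#' Returns a single-echo [MultiEchoSeries-class] carrying the selected
#' echo's magnitude (and phase, when present) together with its echo time.
#' Used for single-echo control analyses, e.g. comparing the second echo of
#' a multi-echo sequence against a matched single-echo acquisition.
#'
#' @param x a [MultiEchoSeries-class].
#' @param echo integer(1), 1-based echo index.
#' @return a [MultiEchoSeries-class] with a single echo.
#' @examples
#' acq <- acquisitionParams(echoTimes = c(15, 40), tr = 2, nFrames = 5,
#'                          gridShape = c(4, 4, 4))
#' run <- simulateRun(acq, tissuePreset("adult"), seed = 1)
#' e2 <- extractEcho(run$series, 2)
#' echoTimes(e2)
#' @export
setGeneric("extractEcho", function(x, echo) standardGeneric("extractEcho"))
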