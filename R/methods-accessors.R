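#' Accessors for mebold S4 classes
#'
#' Small accessor functions replacing direct slot access: echo metadata and
#' voxel data for series, map values for [T2StarMap-class] and
#' [TsnrMap-class], motion and censoring summaries, and connectivity
#' values.
#'
#' @param x an object of the documented class.
#' @param echo integer(1), 1-based echo index.
#' @name accessors
NULL

#' @rdname accessors
setMethod("echoTimes", "MultiEchoSeries", function(x) x@echoTimes)

#' @rdname accessors
setMethod("echoTimes", "AcquisitionParams", function(x) x@echoTimes)

#' @rdname accessors
setMethod("repetitionTime", "MultiEchoSeries", function(x) x@tr)

#' @rdname accessors
setMethod("repetitionTime", "AcquisitionParams", function(x) x@tr)

#' @rdname accessors
setMethod("repetitionTime", "MotionTrace", function(x) x@tr)

#' @rdname accessors
setMethod("nEchoes", "MultiEchoSeries", function(x) length(x@echoTimes))

#' @rdname accessors
setMethod("nFrames", "MultiEchoSeries", function(x)
    dim(x@magnitude[[1L]])[4] - x@nNoiseFrames)

#' @rdname accessors
setMethod("nFrames", "AcquisitionParams", function(x) x@nFrames)

#' @rdname accessors
setMethod("nFrames", "MotionTrace", function(x) nrow(x@params))

#' @rdname accessors
setMethod("nNoiseFrames", "MultiEchoSeries", function(x) x@nNoiseFrames)

#' @rdname accessors
setMethod("nNoiseFrames", "AcquisitionParams", function(x) x@nNoiseFrames)

#' @rdname accessors
setMethod("gridShape", "MultiEchoSeries", function(x)
    dim(x@magnitude[[1L]])[1:3])

#' @rdname accessors
setMethod("gridShape", "AcquisitionParams", function(x) x@gridShape)

#' @rdname accessors
setMethod("magnitudeData", "MultiEchoSeries", function(x, echo) {
    stopifnot(length(echo) == 1L, echo >= 1L, echo <= nEchoes(x))
    x@magnitude[[echo]]
})

#' @rdname accessors
setMethod("phaseData", "MultiEchoSeries", function(x, echo) {
    if (!hasPhase(x))
        stop("series carries no phase data")
    stopifnot(length(echo) == 1L, echo >= 1L, echo <= nEchoes(x))
    x@phase[[echo]]
})

#' @rdname accessors
setMethod("hasPhase", "MultiEchoSeries", function(x) length(x@phase) > 0L)

#' @rdname accessors
setMethod("t2starValues", "T2StarMap", function(x) x@t2star)

#' @rdname accessors
setMethod("r2starValues", "T2StarMap", function(x) x@r2star)

#' @rdname accessors
setMethod("s0Values", "T2StarMap", function(x) x@s0)

#' @rdname accessors
setMethod("validVoxels", "T2StarMap", function(x) x@valid)

#' @rdname accessors
setMethod("validVoxels", "TsnrMap", function(x) x@defined)

#' @rdname accessors
setMethod("motionParams", "MotionTrace", function(x) x@params)

#' @rdname accessors
setMethod("fdSeries", "CensorMask", function(x) x@fd)

#' @rdname accessors
setMethod("retainedFrames", "CensorMask", function(x) x@retained)

#' @rdname accessors
setMethod("pctRetained", "CensorMask", function(x) x@pctRetained)

#' @rdname accessors
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)

#' @rdname accessors
setMethod("nodeKind", "ConnectivityMatrix", function(x) x@nodeKind)

#' @rdname accessors
setMethod("nodeKind", "ReliabilityCurve", function(x) x@nodeKind)

#' @rdname accessors
setMethod("tsnrValues", "TsnrMap", function(x) x@values)

#' @rdname accessors
setMethod("noiseSigma", "NoiseEstimate", function(x) x@sigma)

#' @rdname accessors
setMethod("noiseSource", "NoiseEstimate", function(x) x@source)

setMethod("show", "MultiEchoSeries", function(object) {
    d <- gridShape(object)
    cat(sprintf("MultiEchoSeries: %d echo(es), grid %dx%dx%d, %d frames (+%d noise)\n",
                nEchoes(object), d[1], d[2], d[3],
                nFrames(object), nNoiseFrames(object)))
    cat(sprintf("  TE (ms): %s | TR %.3f s | phase: %s\n",
                paste(format(echoTimes(object), trim = TRUE), collapse = ", "),
                repetitionTime(object),
                if (hasPhase(object)) "yes" else "no"))
})

setMethod("show", "T2StarMap", function(object) {
    v <- object@valid
    t2 <- object@t2star[v]
    cat(sprintf("T2StarMap: %s voxels, %d valid\n",
                paste(dim(object@t2star), collapse = "x"), sum(v)))
    if (length(t2))
        cat(sprintf("  T2* (ms): median %.2f [IQR %.2f-%.2f], bounds [%g, %g]\n",
                    stats::median(t2), stats::quantile(t2, 0.25),
                    stats::quantile(t2, 0.75),
                    object@bounds[1], object@bounds[2]))
})

setMethod("show", "CensorMask", function(object) {
    cat(sprintf("CensorMask: %d frames, FD threshold %g mm, %.1f%% retained\n",
                length(object@fd), object@threshold, object@pctRetained))
})

setMethod("show", "ConnectivityMatrix", function(object) {
    cat(sprintf("ConnectivityMatrix: %d %s nodes (%s), %d frames used\n",
                nrow(object@values), object@nodeKind,
                if (object@fisherZ) "Fisher z" else "Pearson r",
                object@nFramesUsed))
})

setMethod("show", "ReliabilityCurve", function(object) {
    cat(sprintf("ReliabilityCurve (%s nodes, %d permutations):\n",
                object@nodeKind, object@nPermutations))
    print(data.frame(minutes = object@minutesGrid,
                     mean_r = round(object@meanR, 3),
                     sd_r = round(object@sdR, 3)))
})

setMethod("show", "TsnrMap", function(object) {
    v <- object@values[object@defined]
    cat(sprintf("TsnrMap '%s': %s voxels, %d defined",
                object@conditionLabel,
                paste(dim(object@values), collapse = "x"),
                sum(object@defined)))
    if (length(v))
        cat(sprintf(", mean %.2f (SD %.2f)", mean(v), stats::sd(v)))
    cat("\n")
})

setMethod("show", "NoiseEstimate", function(object) {
    cat(sprintf("NoiseEstimate: sigma = %.4g (source: %s)\n",
                object@sigma, object@source))
})
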