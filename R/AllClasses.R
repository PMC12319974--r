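#' @import methods
NULL

#' Acquisition parameters for a multi-echo BOLD run
#'
#' Bundles the sequence parameters needed to simulate or interpret a
#' multi-echo acquisition: echo times, repetition time, frame counts (with
#' trailing pure-noise frames acquired without excitation), grid geometry
#' and voxel size.
#'
#' @slot echoTimes numeric, echo times in ms, strictly increasing, positive.
#' @slot tr numeric(1), repetition time in seconds.
#' @slot nFrames integer(1), number of BOLD frames (noise frames excluded).
#' @slot nNoiseFrames integer(1), number of trailing noise-only frames.
#' @slot gridShape integer(3), volume dimensions in voxels.
#' @slot voxelSize numeric(1), isotropic voxel edge length in mm.
#'
#' @seealso [acquisitionParams()], [fiveEchoPreset()]
#' @export
setClass("AcquisitionParams",
    representation(
        echoTimes = "numeric",
        tr = "numeric",
        nFrames = "integer",
        nNoiseFrames = "integer",
        gridShape = "integer",
        voxelSize = "numeric"
    )
)

setValidity("AcquisitionParams", function(object) {
    msg <- NULL
    te <- object@echoTimes
    if (length(te) < 1L || any(!is.finite(te)) || any(te <= 0))
        msg <- c(msg, "echoTimes must be positive and finite")
    if (length(te) > 1L && any(diff(te) <= 0))
        msg <- c(msg, "echoTimes must be strictly increasing")
    if (length(object@tr) != 1L || object@tr <= 0)
        msg <- c(msg, "tr must be a single positive number (seconds)")
    if (object@nFrames < 2L)
        msg <- c(msg, "nFrames must be >= 2")
    if (object@nNoiseFrames < 0L)
        msg <- c(msg, "nNoiseFrames must be >= 0")
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
        msg <- c(msg, "gridShape must be 3 positive integers")
    if (object@voxelSize <= 0)
        msg <- c(msg, "voxelSize must be positive (mm)")
    if (is.null(msg)) TRUE else msg
})

#' Age-specific tissue preset
#'
#' Marginal T2* distribution (truncated normal) and baseline signal level
#' used by the synthetic tissue-map generator. Shipped presets encode the
#' cortical T2* distributions of an adult (mean 48.89 ms, SD 12.23 ms), a
#' 10-year-old child (59.34 / 13.96 ms) and a newborn infant
#' (93.84 / 27.04 ms): neonatal tissue has longer, more variable T2*
#' because of its higher free-water content and incomplete myelination.
#'
#' @slot label character(1), one of "adult", "child", "infant".
#' @slot t2sMean numeric(1), mean T2* in ms.
#' @slot t2sSD numeric(1), SD of T2* in ms.
#' @slot t2sBounds numeric(2), clipping bounds for sampled maps in ms.
#' @slot s0Mean numeric(1), baseline signal level (arbitrary units).
#'
#' @seealso [tissuePreset()], [makeTissueMaps()]
#' @export
setClass("TissuePreset",
    representation(
        label = "character",
        t2sMean = "numeric",
        t2sSD = "numeric",
        t2sBounds = "numeric",
        s0Mean = "numeric"
    )
)

setValidity("TissuePreset", function(object) {
    msg <- NULL
    if (object@t2sSD <= 0)
        msg <- c(msg, "t2sSD must be positive")
    b <- object@t2sBounds
    if (length(b) != 2L || b[1] >= b[2] || b[1] <= 0)
        msg <- c(msg, "t2sBounds must be an increasing positive pair (ms)")
    else if (object@t2sMean < b[1] || object@t2sMean > b[2])
        msg <- c(msg, "t2sMean must lie within t2sBounds")
    if (object@s0Mean <= 0)
        msg <- c(msg, "s0Mean must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Ground-truth network model for synthetic BOLD
#'
#' Defines the neural covariance structure carried by the simulated BOLD
#' fluctuations. Voxels are grouped into contiguous parcels; each parcel is
#' assigned to one of K networks whose latent time series follow a
#' multivariate normal with covariance \code{neuralCov}. A voxel's
#' fluctuation is a mixture of its network's series and an idiosyncratic
#' component (variance fraction \code{idioFraction}), entering the signal
#' as a transverse relaxation-rate modulation of amplitude
#' \code{deltaR2sAmplitude} (1/s).
#'
#' @slot parcels integer 3D array, parcel label per voxel (0 = outside mask).
#' @slot parcelNetwork integer, network index per parcel.
#' @slot neuralCov symmetric positive-semidefinite network covariance.
#' @slot deltaR2sAmplitude numeric(1), R2* fluctuation scale in 1/s.
#' @slot idioFraction numeric(1) in [0, 1), voxel-level variance fraction.
#'
#' @seealso [networkModel()], [simulateRun()]
#' @export
setClass("NetworkModel",
    representation(
        parcels = "array",
        parcelNetwork = "integer",
        neuralCov = "matrix",
        deltaR2sAmplitude = "numeric",
        idioFraction = "numeric"
    )
)

setValidity("NetworkModel", function(object) {
    msg <- NULL
    C <- object@neuralCov
    if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
        msg <- c(msg, "neuralCov must be symmetric")
    else if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
        msg <- c(msg, "neuralCov must be positive semi-definite")
    lab <- object@parcels[object@parcels > 0L]
    if (length(lab) == 0L)
        msg <- c(msg, "parcels must label at least one in-mask voxel")
    else if (max(lab) > length(object@parcelNetwork))
        msg <- c(msg, "parcel labels exceed parcelNetwork length")
    if (length(object@parcelNetwork) > 0L &&
        (min(object@parcelNetwork) < 1L ||
         max(object@parcelNetwork) > nrow(C)))
        msg <- c(msg, "parcelNetwork indices must point into neuralCov")
    if (object@deltaR2sAmplitude < 0)
        msg <- c(msg, "deltaR2sAmplitude must be >= 0")
    if (object@idioFraction < 0 || object@idioFraction >= 1)
        msg <- c(msg, "idioFraction must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Noise and motion model for synthetic BOLD
#'
#' @slot thermalSigma numeric(1), per-channel (real/imaginary) SD of the
#'   additive complex Gaussian thermal noise, in signal units.
#' @slot respFreqBpm numeric(1), respiratory rate in breaths per minute.
#' @slot respAmplitude numeric(1), respiratory amplitude as fraction of S0.
#' @slot driftAmplitude numeric(1), slow drift amplitude as fraction of S0.
#' @slot motionSpikeProb numeric(1), per-frame probability of a motion spike.
#' @slot motionSpikeMm numeric(1), spike magnitude in mm of displacement.
#' @slot motionSignalGain numeric(1), fractional signal perturbation per mm
#'   of framewise displacement on spike frames.
#'
#' @seealso [noiseModel()], [simulateRun()]
#' @export
setClass("NoiseModel",
    representation(
        thermalSigma = "numeric",
        respFreqBpm = "numeric",
        respAmplitude = "numeric",
        driftAmplitude = "numeric",
        motionSpikeProb = "numeric",
        motionSpikeMm = "numeric",
        motionSignalGain = "numeric"
    )
)

setValidity("NoiseModel", function(object) {
    msg <- NULL
    amps <- c(object@thermalSigma, object@respAmplitude,
              object@driftAmplitude, object@motionSpikeMm,
              object@motionSignalGain)
    if (any(amps < 0))
        msg <- c(msg, "amplitudes must be >= 0")
    p <- object@motionSpikeProb
    if (p < 0 || p > 1)
        msg <- c(msg, "motionSpikeProb must be in [0, 1]")
    if (object@respFreqBpm < 0)
        msg <- c(msg, "respFreqBpm must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Multi-echo BOLD series
#'
#' Central signal container: per-echo 4D magnitude (and optionally phase)
#' volumes with echo times, repetition time and the count of trailing
#' noise-only frames. The time dimension includes the noise frames, which
#' always sit at the end of the run.
#'
#' @slot magnitude list of 4D arrays (x, y, z, t), one per echo.
#' @slot phase list of 4D arrays in radians, same shapes; may be empty.
#' @slot echoTimes numeric, echo times in ms (one per list element).
#' @slot tr numeric(1), repetition time in seconds.
#' @slot nNoiseFrames integer(1), trailing noise-only frames.
#'
#' @seealso [multiEchoSeries()], [simulateRun()], [extractEcho()]
#' @export
setClass("MultiEchoSeries",
    representation(
        magnitude = "list",
        phase = "list",
        echoTimes = "numeric",
        tr = "numeric",
        nNoiseFrames = "integer"
    )
)

setValidity("MultiEchoSeries", function(object) {
    msg <- NULL
    ne <- length(object@echoTimes)
    if (length(object@magnitude) != ne)
        msg <- c(msg, "one magnitude array per echo time is required")
    dims <- lapply(object@magnitude, dim)
    if (length(dims) > 0L) {
        if (any(vapply(dims, length, 1L) != 4L))
            msg <- c(msg, "magnitude arrays must be 4D (x, y, z, t)")
        else if (length(unique(lapply(dims, identity))) != 1L)
            msg <- c(msg, "all echoes must share the same dimensions")
        else if (dims[[1]][4] <= object@nNoiseFrames)
            msg <- c(msg, "need at least one BOLD frame beyond noise frames")
    }
    if (length(object@phase) > 0L) {
        if (length(object@phase) != ne)
            msg <- c(msg, "phase must be empty or have one array per echo")
        else if (!identical(lapply(object@phase, dim), dims))
            msg <- c(msg, "phase arrays must match magnitude dimensions")
    }
    if (length(object@tr) != 1L || object@tr <= 0)
        msg <- c(msg, "tr must be a single positive number")
    if (ne > 1L && any(diff(object@echoTimes) <= 0))
        msg <- c(msg, "echoTimes must be strictly increasing")
    if (is.null(msg)) TRUE else msg
})

#' Voxelwise T2* map
#'
#' Result of the monoexponential fit across echoes: T2* (ms), baseline
#' signal S0, the derived relaxation rate R2* = 1000/T2* (1/s), per-voxel
#' fit RMSE (in log-signal units), the number of echoes used and a validity
#' flag. T2* is clipped to the configured bounds.
#'
#' @slot t2star,s0,r2star,fitRMSE numeric 3D arrays.
#' @slot nEchoesUsed integer 3D array.
#' @slot valid logical 3D array; FALSE where the fit was not possible or
#'   hit degenerate data.
#' @slot bounds numeric(2), the T2* clipping bounds in ms.
#'
#' @seealso [fitT2Star()], [optimalCombine()], [weightSummary()]
#' @export
setClass("T2StarMap",
    representation(
        t2star = "array",
        s0 = "array",
        r2star = "array",
        fitRMSE = "array",
        nEchoesUsed = "array",
        valid = "array",
        bounds = "numeric"
    )
)

setValidity("T2StarMap", function(object) {
    msg <- NULL
    d <- dim(object@t2star)
    for (nm in c("s0", "r2star", "fitRMSE", "nEchoesUsed", "valid"))
        if (!identical(dim(slot(object, nm)), d))
            msg <- c(msg, sprintf("slot '%s' dimensions differ from t2star", nm))
    v <- object@valid
    t2 <- object@t2star[v]
    if (length(t2) > 0L) {
        if (any(t2 < object@bounds[1] - 1e-9 | t2 > object@bounds[2] + 1e-9))
            msg <- c(msg, "valid t2star values must lie within bounds")
        r2 <- object@r2star[v]
        if (max(abs(r2 * t2 - 1000)) > 1e-6)
            msg <- c(msg, "r2star must equal 1000/t2star (ms <-> 1/s)")
    }
    if (any(object@fitRMSE[v] < 0))
        msg <- c(msg, "fitRMSE must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Rigid-body motion trace
#'
#' Six motion parameters per frame: translations (mm) then rotations
#' (radians). Noise frames are excluded.
#'
#' @slot params numeric matrix, frames x 6, columns
#'   trans_x, trans_y, trans_z, rot_x, rot_y, rot_z.
#' @slot tr numeric(1), repetition time in seconds.
#'
#' @seealso [motionTrace()], [framewiseDisplacement()], [bandstopMotion()]
#' @export
setClass("MotionTrace",
    representation(params = "matrix", tr = "numeric")
)

setValidity("MotionTrace", function(object) {
    msg <- NULL
    if (ncol(object@params) != 6L)
        msg <- c(msg, "params must have 6 columns (3 translations, 3 rotations)")
    if (any(!is.finite(object@params)))
        msg <- c(msg, "motion parameters must be finite")
    if (length(object@tr) != 1L || object@tr <= 0)
        msg <- c(msg, "tr must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Frame censoring mask
#'
#' Framewise displacement with a threshold and the implied retained-frame
#' mask. A frame is retained iff its FD does not exceed the threshold
#' (censoring is strict: "FD > threshold" is removed); the first frame has
#' FD 0 by convention and is always retained.
#'
#' @slot fd numeric, framewise displacement in mm per frame.
#' @slot threshold numeric(1), censoring threshold in mm.
#' @slot retained logical per frame.
#' @slot pctRetained numeric(1), percent of frames retained.
#'
#' @seealso [censorFrames()], [selectRuns()]
#' @export
setClass("CensorMask",
    representation(
        fd = "numeric",
        threshold = "numeric",
        retained = "logical",
        pctRetained = "numeric"
    )
)

setValidity("CensorMask", function(object) {
    msg <- NULL
    if (length(object@fd) != length(object@retained))
        msg <- c(msg, "fd and retained must have equal length")
    else {
        if (!identical(object@retained, object@fd <= object@threshold))
            msg <- c(msg, "retained must equal fd <= threshold")
        pct <- 100 * mean(object@retained)
        if (abs(pct - object@pctRetained) > 1e-8)
            msg <- c(msg, "pctRetained inconsistent with retained")
    }
    if (object@threshold <= 0)
        msg <- c(msg, "threshold must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Functional connectivity matrix
#'
#' Node-by-node Pearson correlations (or Fisher z) over retained frames,
#' with provenance: node kind, frames used and the FD threshold that
#' produced the censoring.
#'
#' @slot values numeric matrix, symmetric; unit diagonal in r form.
#' @slot nodeKind character(1), "dense" or "parcel".
#' @slot fisherZ logical(1), whether values are Fisher z-transformed.
#' @slot nFramesUsed integer(1).
#' @slot fdThreshold numeric(1), mm; NA when no censoring was applied.
#'
#' @seealso [connectivity()]
#' @export
setClass("ConnectivityMatrix",
    representation(
        values = "matrix",
        nodeKind = "character",
        fisherZ = "logical",
        nFramesUsed = "integer",
        fdThreshold = "numeric"
    )
)

setValidity("ConnectivityMatrix", function(object) {
    msg <- NULL
    V <- object@values
    if (nrow(V) != ncol(V))
        msg <- c(msg, "values must be square")
    else {
        fin <- is.finite(V) & is.finite(t(V))
        if (max(abs(V[fin] - t(V)[fin]), 0) > 1e-8)
            msg <- c(msg, "values must be symmetric")
        if (!object@fisherZ && any(abs(V[is.finite(V)]) > 1 + 1e-8))
            msg <- c(msg, "correlations must satisfy |r| <= 1")
    }
    if (!object@nodeKind %in% c("dense", "parcel"))
        msg <- c(msg, "nodeKind must be 'dense' or 'parcel'")
    if (is.null(msg)) TRUE else msg
})

#' Split-half reliability curve
#'
#' Mean and SD (across run-order permutations) of split-half reliability as
#' a function of the amount of data, plus the per-node reliability map at
#' the largest data amount.
#'
#' @slot minutesGrid numeric, strictly increasing data amounts in minutes.
#' @slot meanR,sdR numeric per grid point.
#' @slot nPermutations integer(1).
#' @slot nodeKind character(1), "dense" or "parcel".
#' @slot nodeReliability numeric, per-node mean reliability at max(minutesGrid).
#'
#' @seealso [splitHalfReliability()], [reliabilityEquivalentMinutes()]
#' @export
setClass("ReliabilityCurve",
    representation(
        minutesGrid = "numeric",
        meanR = "numeric",
        sdR = "numeric",
        nPermutations = "integer",
        nodeKind = "character",
        nodeReliability = "numeric"
    )
)

setValidity("ReliabilityCurve", function(object) {
    msg <- NULL
    g <- object@minutesGrid
    if (length(g) > 1L && any(diff(g) <= 0))
        msg <- c(msg, "minutesGrid must be strictly increasing")
    if (length(object@meanR) != length(g) || length(object@sdR) != length(g))
        msg <- c(msg, "meanR/sdR must match minutesGrid length")
    if (isTRUE(any(abs(object@meanR) > 1 + 1e-8)))
        msg <- c(msg, "|meanR| must be <= 1")
    if (isTRUE(any(object@sdR < 0)))
        msg <- c(msg, "sdR must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Temporal SNR map
#'
#' Voxelwise temporal mean divided by temporal SD. Voxels with zero
#' temporal SD are flagged undefined rather than set to infinity, and are
#' excluded from summaries.
#'
#' @slot values numeric 3D array; NA where undefined.
#' @slot defined logical 3D array.
#' @slot runsUsed integer, indices of the runs averaged into this map.
#' @slot conditionLabel character(1), free-text condition tag.
#'
#' @seealso [tsnrMap()], [averageTsnr()]
#' @export
setClass("TsnrMap",
    representation(
        values = "array",
        defined = "array",
        runsUsed = "integer",
        conditionLabel = "character"
    )
)

setValidity("TsnrMap", function(object) {
    msg <- NULL
    if (!identical(dim(object@values), dim(object@defined)))
        msg <- c(msg, "values and defined must share dimensions")
    v <- object@values[object@defined]
    if (any(!is.finite(v)))
        msg <- c(msg, "defined voxels must hold finite tSNR values")
    if (is.null(msg)) TRUE else msg
})

#' Thermal noise level estimate
#'
#' @slot sigma numeric(1), per-channel (real/imaginary) noise SD.
#' @slot source character(1), "noise_frames" or "theoretical".
#' @slot theoreticalFactor numeric(1), the 1/sqrt(2) scaling recorded when
#'   the theoretical fallback is used (NA otherwise).
#'
#' @seealso [estimateNoiseSigma()]
#' @export
setClass("NoiseEstimate",
    representation(
        sigma = "numeric",
        source = "character",
        theoreticalFactor = "numeric"
    )
)

setValidity("NoiseEstimate", function(object) {
    msg <- NULL
    if (length(object@sigma) != 1L || object@sigma <= 0)
        msg <- c(msg, "sigma must be a single positive number")
    if (!object@source %in% c("noise_frames", "theoretical"))
        msg <- c(msg, "source must be 'noise_frames' or 'theoretical'")
    if (is.null(msg)) TRUE else msg
})
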