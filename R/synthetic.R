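#' Construct acquisition parameters
#'
#' @param echoTimes numeric, echo times in ms (strictly increasing).
#' @param tr numeric(1), repetition time in seconds.
#' @param nFrames integer(1), number of BOLD frames (>= 2).
#' @param nNoiseFrames integer(1), trailing noise-only frames (>= 0).
#' @param gridShape integer(3), volume dimensions in voxels.
#' @param voxelSize numeric(1), isotropic voxel size in mm.
#' @return an [AcquisitionParams-class].
#' @seealso [fiveEchoPreset()] for the five-echo protocol used throughout
#'   the examples.
#' @export
acquisitionParams <- function(echoTimes, tr, nFrames, nNoiseFrames = 0L,
                              gridShape = c(24L, 24L, 24L), voxelSize = 2) {
    new("AcquisitionParams",
        echoTimes = as.numeric(echoTimes), tr = as.numeric(tr),
        nFrames = as.integer(nFrames),
        nNoiseFrames = as.integer(nNoiseFrames),
        gridShape = as.integer(gridShape), voxelSize = as.numeric(voxelSize))
}

#' Five-echo acquisition preset
#'
#' The five-echo multiband protocol used as the reference acquisition:
#' echo times 14.2, 38.93, 63.66, 88.39, 113.12 ms, TR 1.761 s, three
#' noise frames appended to each run.
#'
#' @param nFrames integer(1), number of BOLD frames.
#' @param gridShape integer(3), volume dimensions.
#' @param voxelSize numeric(1), mm.
#' @return an [AcquisitionParams-class].
#' @examples
#' fiveEchoPreset(nFrames = 100)
#' @export
fiveEchoPreset <- function(nFrames = 200L, gridShape = c(24L, 24L, 24L),
                           voxelSize = 2) {
    acquisitionParams(
        echoTimes = c(14.2, 38.93, 63.66, 88.39, 113.12),
        tr = 1.761, nFrames = nFrames, nNoiseFrames = 3L,
        gridShape = gridShape, voxelSize = voxelSize)
}

#' Age-specific tissue presets
#'
#' Returns the T2* distribution parameters for one of the three shipped age
#' groups. Means and SDs follow cortical T2* distributions at 3 T: adult
#' 48.89 (SD 12.23) ms, child 59.34 (13.96) ms, infant 93.84 (27.04) ms.
#' Bounds are wide enough that truncation is negligible (they cover roughly
#' +/- 3.5 SD) while excluding non-physical values.
#'
#' @param label character(1), "adult", "child" or "infant".
#' @param s0Mean numeric(1), baseline signal level.
#' @return a [TissuePreset-class].
#' @examples
#' tissuePreset("infant")
#' @export
tissuePreset <- function(label = c("adult", "child", "infant"), s0Mean = 100) {
    label <- match.arg(label)
    p <- switch(label,
        adult  = list(mean = 48.89, sd = 12.23, bounds = c(8, 100)),
        child  = list(mean = 59.34, sd = 13.96, bounds = c(9, 115)),
        infant = list(mean = 93.84, sd = 27.04, bounds = c(12, 195)))
    new("TissuePreset", label = label, t2sMean = p$mean, t2sSD = p$sd,
        t2sBounds = p$bounds, s0Mean = as.numeric(s0Mean))
}

#' Construct a custom tissue preset
#'
#' @param t2sMean,t2sSD numeric(1), T2* mean and SD in ms.
#' @param t2sBounds numeric(2), clipping bounds in ms.
#' @param s0Mean numeric(1), baseline signal level.
#' @param label character(1), free label.
#' @return a [TissuePreset-class].
#' @export
customTissuePreset <- function(t2sMean, t2sSD, t2sBounds, s0Mean = 100,
                               label = "custom") {
    new("TissuePreset", label = label, t2sMean = as.numeric(t2sMean),
        t2sSD = as.numeric(t2sSD), t2sBounds = as.numeric(t2sBounds),
        s0Mean = as.numeric(s0Mean))
}

#' Construct a ground-truth network model
#'
#' Builds a default network model on a spherical brain mask: the mask is
#' tiled into contiguous cubic parcels (intersected with the mask), parcels
#' are assigned cyclically to \code{nNetworks} networks, and the network
#' covariance defaults to a banded correlation matrix
#' \code{0.5^|i - j|}. The BOLD fluctuation enters the signal as a
#' relaxation-rate modulation of amplitude \code{deltaR2sAmplitude} (1/s),
#' so the fractional signal change scales with echo time, as it does
#' physically.
#'
#' @param gridShape integer(3), volume dimensions in voxels.
#' @param nNetworks integer(1), number of networks.
#' @param parcelEdge integer(1), parcel edge length in voxels.
#' @param neuralCov optional K x K covariance matrix across networks.
#' @param deltaR2sAmplitude numeric(1), R2* fluctuation SD in 1/s. The
#'   default 0.3 gives ~1.7% fractional signal change at TE = 55 ms.
#' @param idioFraction numeric(1) in [0, 1), fraction of each voxel's
#'   fluctuation variance that is voxel-specific rather than shared with
#'   its network (makes parcel-average series cleaner than single voxels,
#'   as in real data).
#' @param maskRadius numeric(1), sphere radius in voxels; default just
#'   inside the grid.
#' @return a [NetworkModel-class].
#' @examples
#' nm <- networkModel(c(16, 16, 16), nNetworks = 3)
#' table(nm@parcelNetwork)
#' @export
networkModel <- function(gridShape, nNetworks = 5L, parcelEdge = NULL,
                         neuralCov = NULL, deltaR2sAmplitude = 0.3,
                         idioFraction = 0.3, maskRadius = NULL) {
    gridShape <- as.integer(gridShape)
    stopifnot(length(gridShape) == 3L, all(gridShape >= 4L))
    if (is.null(maskRadius))
        maskRadius <- min(gridShape) / 2 - 1
    if (is.null(parcelEdge))
        parcelEdge <- max(3L, floor(min(gridShape) / 4))
    ctr <- (gridShape + 1) / 2
    ax <- lapply(1:3, function(k) seq_len(gridShape[k]) - ctr[k])
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
    mask <- d2 <= maskRadius^2
    blockIdx <- function(n) (seq_len(n) - 1L) %/% parcelEdge
    bx <- blockIdx(gridShape[1]); by <- blockIdx(gridShape[2])
    bz <- blockIdx(gridShape[3])
    nb <- c(max(bx), max(by), max(bz)) + 1L
    block <- outer(outer(bx, by * nb[1], "+"), bz * nb[1] * nb[2], "+") + 1L
    parcels <- array(0L, gridShape)
    parcels[mask] <- block[mask]
    # compact labels to 1..P over non-empty parcels
    labs <- sort(unique(parcels[parcels > 0L]))
    parcels[parcels > 0L] <- match(parcels[parcels > 0L], labs)
    nP <- length(labs)
    if (is.null(neuralCov)) {
        K <- as.integer(nNetworks)
        neuralCov <- 0.5^abs(outer(seq_len(K), seq_len(K), "-"))
    }
    K <- nrow(neuralCov)
    new("NetworkModel", parcels = parcels,
        parcelNetwork = as.integer((seq_len(nP) - 1L) %% K + 1L),
        neuralCov = neuralCov,
        deltaR2sAmplitude = as.numeric(deltaR2sAmplitude),
        idioFraction = as.numeric(idioFraction))
}

#' Construct a noise and motion model
#'
#' Defaults emulate a compliant adult at 3 T: respiration at 15 breaths
#' per minute (the adult band-stop target range is 12-18 bpm), ~1% slow
#' drift and respiratory amplitude relative to baseline signal, occasional
#' motion spikes of 1 mm with 5% per-frame probability on top of a slow
#' drifting baseline. The default thermal level (per-channel SD 1 at
#' baseline S0 = 100) is calibrated so that raw single-run temporal SNR
#' lands in the 40-70 range typical of adult 3 T precision fMRI at 2 mm.
#'
#' @param thermalSigma numeric(1), per-channel complex noise SD.
#' @param respFreqBpm numeric(1), respiratory rate (breaths/min).
#' @param respAmplitude numeric(1), respiratory amplitude as a fraction of
#'   the local baseline signal.
#' @param driftAmplitude numeric(1), drift amplitude as a fraction of the
#'   local baseline signal.
#' @param motionSpikeProb numeric(1) in [0, 1].
#' @param motionSpikeMm numeric(1), spike displacement in mm.
#' @param motionSignalGain numeric(1), fractional signal perturbation per
#'   mm of spike displacement.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(thermalSigma = 1, respFreqBpm = 15,
                       respAmplitude = 0.01, driftAmplitude = 0.01,
                       motionSpikeProb = 0.05, motionSpikeMm = 1,
                       motionSignalGain = 0.01) {
    new("NoiseModel", thermalSigma = as.numeric(thermalSigma),
        respFreqBpm = as.numeric(respFreqBpm),
        respAmplitude = as.numeric(respAmplitude),
        driftAmplitude = as.numeric(driftAmplitude),
        motionSpikeProb = as.numeric(motionSpikeProb),
        motionSpikeMm = as.numeric(motionSpikeMm),
        motionSignalGain = as.numeric(motionSignalGain))
}

#' Construct a multi-echo series from arrays
#'
#' @param magnitude list of 4D arrays (x, y, z, t), one per echo.
#' @param echoTimes numeric, echo times in ms.
#' @param tr numeric(1), repetition time in seconds.
#' @param phase optional list of phase arrays (radians).
#' @param nNoiseFrames integer(1), trailing noise-only frames.
#' @return a [MultiEchoSeries-class].
#' @export
multiEchoSeries <- function(magnitude, echoTimes, tr, phase = list(),
                            nNoiseFrames = 0L) {
    if (is.array(magnitude)) magnitude <- list(magnitude)
    if (is.array(phase)) phase <- list(phase)
    new("MultiEchoSeries", magnitude = magnitude, phase = phase,
        echoTimes = as.numeric(echoTimes), tr = as.numeric(tr),
        nNoiseFrames = as.integer(nNoiseFrames))
}

#' Construct a motion trace
#'
#' @param params numeric matrix, frames x 6 (translations in mm, then
#'   rotations in radians).
#' @param tr numeric(1), repetition time in seconds.
#' @return a [MotionTrace-class].
#' @export
motionTrace <- function(params, tr) {
    params <- as.matrix(params)
    colnames(params) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    new("MotionTrace", params = params, tr = as.numeric(tr))
}

#' Sample ground-truth tissue maps
#'
#' Draws a voxelwise T2* map from the preset's truncated normal with mild
#' spatial autocorrelation: an i.i.d. Gaussian field is smoothed with a
#' 1-voxel-SD kernel, restandardized to the preset mean/SD (smoothing
#' shrinks the marginal SD, so the field is rescaled to restore it), then
#' clipped to the preset bounds. The S0 map is a smooth positive field
#' around the preset's baseline level.
#'
#' @param preset a [TissuePreset-class].
#' @param gridShape integer(3).
#' @param seed integer(1), RNG seed; identical seeds give identical maps.
#' @param smoothSigma numeric(1), smoothing kernel SD in voxels.
#' @return list with 3D arrays \code{t2star} (ms) and \code{s0}.
#' @examples
#' maps <- makeTissueMaps(tissuePreset("adult"), c(16, 16, 16), seed = 1)
#' mean(maps$t2star)
#' @export
makeTissueMaps <- function(preset, gridShape, seed, smoothSigma = 1) {
    stopifnot(is(preset, "TissuePreset"))
    validObject(preset)
    gridShape <- as.integer(gridShape)
    stopifnot(length(gridShape) == 3L, all(gridShape >= 1L))
    withSeed(seed, {
        f <- array(stats::rnorm(prod(gridShape)), gridShape)
        f <- gaussianSmooth3d(f, smoothSigma)
        f <- (f - mean(f)) / stats::sd(as.vector(f))
        t2star <- pmin(pmax(preset@t2sMean + preset@t2sSD * f,
                            preset@t2sBounds[1]), preset@t2sBounds[2])
        g <- gaussianSmooth3d(array(stats::rnorm(prod(gridShape)), gridShape),
                              smoothSigma)
        g <- (g - mean(g)) / stats::sd(as.vector(g))
        s0 <- preset@s0Mean * pmax(1 + 0.1 * g, 0.2)
        list(t2star = t2star, s0 = s0)
    })
}

# Evaluate expr with a local RNG seed, restoring the global RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Simulate a multi-echo BOLD run with known ground truth
#'
#' Generates per-echo magnitude and phase series following a
#' monoexponential decay model with BOLD contrast entering through
#' relaxation-rate fluctuations:
#' \deqn{S_e(v, t) = S_0(v) \exp(-TE_e / T2^*(v) - TE_e \Delta R_2^*(v, t) / 1000)}
#' with TE and T2* in ms and \eqn{\Delta R_2^*} in 1/s. The fluctuation
#' \eqn{\Delta R_2^*(v, t) = -A z(v, t)} carries the network covariance of
#' the supplied [NetworkModel-class] through temporally autocorrelated
#' (AR(1), ~8 s timescale) latent network series, mixed with a
#' voxel-specific component. Respiratory oscillation and slow drift are
#' added in proportion to the local baseline signal; motion is simulated
#' as parameter traces (slow wander plus step-like spikes) with an
#' optional global signal perturbation on spike frames; and complex
#' Gaussian thermal noise of per-channel SD \code{thermalSigma} is added
#' to the real and imaginary channels before taking magnitude and phase.
#' Trailing noise frames contain thermal noise only. Voxels outside the
#' network model's brain mask carry no signal.
#'
#' @param acq an [AcquisitionParams-class].
#' @param tissue a [TissuePreset-class], or a list with 3D arrays
#'   \code{t2star} and \code{s0} (as from [makeTissueMaps()]).
#' @param network a [NetworkModel-class]; default built on the grid.
#' @param noise a [NoiseModel-class]; default [noiseModel()].
#' @param seed integer(1); identical seeds give identical output.
#' @param arTimescale numeric(1), AR(1) timescale of the neural series in
#'   seconds.
#' @return list with elements \code{series} ([MultiEchoSeries-class]),
#'   \code{motion} ([MotionTrace-class]) and \code{truth}: a list holding
#'   \code{t2star}, \code{s0}, \code{mask}, \code{parcels},
#'   \code{parcelNetwork}, \code{neuralTimeseries} (frames x networks),
#'   \code{deltaR2s} (in-mask voxels x frames, 1/s),
#'   \code{trueConnectivity} (network correlation matrix), \code{fdTrue}
#'   and \code{spikeFrames}.
#' @examples
#' acq <- acquisitionParams(c(15, 40, 65), tr = 2, nFrames = 20,
#'                          nNoiseFrames = 2, gridShape = c(12, 12, 12))
#' run <- simulateRun(acq, tissuePreset("adult"), seed = 7)
#' run$series
#' @export
simulateRun <- function(acq, tissue, network = NULL, noise = NULL, seed,
                        arTimescale = 8) {
    stopifnot(is(acq, "AcquisitionParams"))
    validObject(acq)
    if (is.null(network))
        network <- networkModel(acq@gridShape)
    if (is.null(noise))
        noise <- noiseModel()
    validObject(network); validObject(noise)
    stopifnot(identical(dim(network@parcels), as.integer(acq@gridShape)))

    if (is(tissue, "TissuePreset"))
        tissue <- makeTissueMaps(tissue, acq@gridShape, seed = seed + 1L)
    stopifnot(identical(dim(tissue$t2star), as.integer(acq@gridShape)))
    te <- acq@echoTimes
    if (max(te) > 5 * max(tissue$t2star))
        warning("longest echo time exceeds 5x the maximum T2*: ",
                "late-echo signal will underflow")

    nT <- acq@nFrames
    nN <- acq@nNoiseFrames
    grid <- acq@gridShape
    mask <- network@parcels > 0L
    vIdx <- which(mask)
    nV <- length(vIdx)
    t2v <- tissue$t2star[vIdx]
    s0v <- tissue$s0[vIdx]
    K <- nrow(network@neuralCov)
    corNet <- stats::cov2cor(network@neuralCov)

    withSeed(seed, {
        # latent network series: AR(1) with stationary covariance neuralCov
        phi <- exp(-acq@tr / arTimescale)
        innov <- rmvn(nT, network@neuralCov)
        zNet <- matrix(0, nT, K)
        zNet[1L, ] <- innov[1L, ]
        for (t in 2:nT)
            zNet[t, ] <- phi * zNet[t - 1L, ] + sqrt(1 - phi^2) * innov[t, ]
        # voxel series: network share + idiosyncratic AR(1) share
        f <- network@idioFraction
        netOfVox <- network@parcelNetwork[network@parcels[vIdx]]
        zVox <- sqrt(1 - f) * t(zNet)[netOfVox, , drop = FALSE]
        if (f > 0) {
            idio <- matrix(stats::rnorm(nV * nT), nV, nT)
            for (t in 2:nT)
                idio[, t] <- phi * idio[, t - 1L] +
                    sqrt(1 - phi^2) * idio[, t]
            zVox <- zVox + sqrt(f) * idio
        }
        deltaR2s <- -network@deltaR2sAmplitude * zVox   # 1/s, in-mask x time

        # physiological and motion structure
        respW <- gaussianSmooth3d(array(stats::runif(prod(grid)), grid), 2)
        respW <- (respW - min(respW)) / max(diff(range(respW)), 1e-12)
        respPhase <- stats::runif(1, 0, 2 * pi)
        fHz <- noise@respFreqBpm / 60
        tt <- seq_len(nT) - 1L
        respT <- sin(2 * pi * fHz * acq@tr * tt + respPhase)
        driftT <- seq(-1, 1, length.out = nT)

        walkSdT <- 0.008; walkSdR <- 1.2e-4
        params <- cbind(
            vapply(1:3, function(j) cumsum(stats::rnorm(nT, 0, walkSdT)),
                   numeric(nT)),
            vapply(1:3, function(j) cumsum(stats::rnorm(nT, 0, walkSdR)),
                   numeric(nT)))
        spikeFrames <- which(stats::runif(nT) < noise@motionSpikeProb)
        spikeFrames <- spikeFrames[spikeFrames > 1L]
        for (t in spikeFrames) {
            col <- sample.int(3L, 1L)
            params[t:nT, col] <- params[t:nT, col] +
                sample(c(-1, 1), 1L) * noise@motionSpikeMm
        }
        motion <- motionTrace(params, tr = acq@tr)
        fdTrue <- framewiseDisplacement(motion)
        frameGain <- rep(1, nT)
        if (length(spikeFrames) && noise@motionSignalGain > 0)
            frameGain[spikeFrames] <- 1 - pmin(
                noise@motionSignalGain * fdTrue[spikeFrames], 0.5)

        phaseMap <- gaussianSmooth3d(array(stats::rnorm(prod(grid)), grid), 3)
        phaseMap <- 0.2 * phaseMap / max(stats::sd(as.vector(phaseMap)), 1e-12)
        phiV <- phaseMap[vIdx]

        nTot <- nT + nN
        magnitude <- vector("list", length(te))
        phase <- vector("list", length(te))
        for (e in seq_along(te)) {
            base <- s0v * exp(-te[e] / t2v)              # in-mask baseline
            S <- base * exp(-(te[e] / 1000) * deltaR2s)  # nV x nT
            S <- S + base * (noise@respAmplitude * (respW[vIdx] %o% respT) +
                             noise@driftAmplitude * outer(rep(1, nV), driftT))
            S <- sweep(S, 2L, frameGain, "*")
            full <- matrix(0, prod(grid), nTot)
            full[vIdx, seq_len(nT)] <- S
            sig <- noise@thermalSigma
            reIm <- full * cos(c(phaseMap)) +
                if (sig > 0) stats::rnorm(length(full), 0, sig) else 0
            imIm <- full * sin(c(phaseMap)) +
                if (sig > 0) stats::rnorm(length(full), 0, sig) else 0
            magnitude[[e]] <- array(sqrt(reIm^2 + imIm^2), c(grid, nTot))
            phase[[e]] <- array(atan2(imIm, reIm), c(grid, nTot))
        }
        series <- multiEchoSeries(magnitude, echoTimes = te, tr = acq@tr,
                                  phase = phase, nNoiseFrames = nN)
        truth <- list(
            t2star = tissue$t2star, s0 = tissue$s0, mask = mask,
            parcels = network@parcels,
            parcelNetwork = network@parcelNetwork,
            neuralTimeseries = zNet, deltaR2s = deltaR2s,
            trueConnectivity = corNet, fdTrue = fdTrue,
            spikeFrames = spikeFrames)
        list(series = series, motion = motion, truth = truth)
    })
}

#' @rdname extractEcho
setMethod("extractEcho", "MultiEchoSeries", function(x, echo) {
    echo <- as.integer(echo)
    if (length(echo) != 1L || echo < 1L || echo > nEchoes(x))
        stop("echo index out of range: ", echo)
    multiEchoSeries(
        magnitude = x@magnitude[echo],
        echoTimes = x@echoTimes[echo], tr = x@tr,
        phase = if (hasPhase(x)) x@phase[echo] else list(),
        nNoiseFrames = x@nNoiseFrames)
})
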