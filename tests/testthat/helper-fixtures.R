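# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

fiveTE <- c(14.2, 38.93, 63.66, 88.39, 113.12)

# small five-echo acquisition for fast end-to-end tests
smallAcq <- function(nFrames = 40L, grid = c(14L, 14L, 14L),
                     nNoiseFrames = 3L) {
    acquisitionParams(fiveTE, tr = 1.761, nFrames = nFrames,
                      nNoiseFrames = nNoiseFrames, gridShape = grid)
}

# a quiet network/noise pairing: no physiological or motion structure
quietNoise <- function(thermalSigma = 0) {
    noiseModel(thermalSigma = thermalSigma, respAmplitude = 0,
               driftAmplitude = 0, motionSpikeProb = 0)
}

staticNetwork <- function(grid, deltaR2sAmplitude = 0, ...) {
    networkModel(grid, deltaR2sAmplitude = deltaR2sAmplitude, ...)
}

# standard noisy run reused across denoise/t2star/metrics tests
noisyRun <- function() cached("noisyRun", {
    simulateRun(smallAcq(), tissuePreset("adult"),
                noise = noiseModel(thermalSigma = 5, respAmplitude = 0,
                                   driftAmplitude = 0, motionSpikeProb = 0),
                seed = 42)
})

# its noiseless twin: identical signal draws, no thermal noise
noiselessTwin <- function() cached("noiselessTwin", {
    simulateRun(smallAcq(), tissuePreset("adult"),
                noise = noiseModel(thermalSigma = 0, respAmplitude = 0,
                                   driftAmplitude = 0, motionSpikeProb = 0),
                seed = 42)
})

denoisedRun <- function() cached("denoisedRun", {
    nordicDenoiseRun(noisyRun()$series, patchEdge = 7, mcDraws = 3, seed = 9)
})

# Synthetic node-series generator: each run is an independent realization
# of nNodes series with a shared latent (network) structure. Nodes come in
# groups of `groupSize` sharing one latent loading (like voxels of one
# parcel), plus node-specific noise of SD noiseSd.
makeNodeRuns <- function(nRuns, nNodes = 40, nFramesPerRun = 400,
                         nLatent = 5, noiseSd = 1, seed = 1,
                         groupSize = 1) {
    set.seed(seed)
    nGroups <- nNodes / groupSize
    Lg <- matrix(rnorm(nGroups * nLatent), nGroups, nLatent) / sqrt(nLatent)
    L <- Lg[rep(seq_len(nGroups), each = groupSize), , drop = FALSE]
    lapply(seq_len(nRuns), function(r) {
        Z <- matrix(rnorm(nLatent * nFramesPerRun), nLatent)
        L %*% Z + noiseSd * matrix(rnorm(nNodes * nFramesPerRun), nNodes)
    })
}

# Frobenius norm that handles complex matrices
frob <- function(X) sqrt(sum(Mod(X)^2))

# in-mask voxel matrix of the first nFrames of one echo
echoMatrix <- function(series, echo, mask) {
    nT <- nFrames(series)
    m <- magnitudeData(series, echo)
    matrix(m, prod(dim(m)[1:3]), dim(m)[4])[as.vector(mask),
                                            seq_len(nT), drop = FALSE]
}
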