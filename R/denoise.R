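#' Estimate the thermal noise level of a run
#'
#' With trailing noise frames (acquired without excitation), the
#' per-channel noise SD is the pooled SD of the real and imaginary parts of
#' the complex data over all noise-frame voxels and echoes. Without noise
#' frames, a theoretical fallback is available: the per-channel SD is taken
#' as 1/sqrt(2) times a robust SD of the magnitude fluctuations in the most
#' signal-free region of the volume (the factor converts a magnitude-scale
#' spread to the per-channel scale under complex Gaussian noise), and the
#' estimate is flagged \code{source = "theoretical"}.
#'
#' @param series a [MultiEchoSeries-class].
#' @param method "noise_frames" (requires \code{nNoiseFrames >= 1}) or
#'   "theoretical".
#' @return a [NoiseEstimate-class].
#' @examples
#' acq <- acquisitionParams(c(15, 40), tr = 2, nFrames = 10, nNoiseFrames = 3,
#'                          gridShape = c(10, 10, 10))
#' run <- simulateRun(acq, tissuePreset("adult"),
#'                    noise = noiseModel(thermalSigma = 3), seed = 1)
#' estimateNoiseSigma(run$series)
#' @export
estimateNoiseSigma <- function(series,
                               method = c("noise_frames", "theoretical")) {
    stopifnot(is(series, "MultiEchoSeries"))
    method <- match.arg(method)
    if (method == "noise_frames") {
        nN <- nNoiseFrames(series)
        if (nN < 1L)
            stop("series has no noise frames; request method = 'theoretical'")
        if (!hasPhase(series))
            stop("noise-frame estimation needs phase data to form complex channels")
        nTot <- dim(series@magnitude[[1L]])[4]
        idx <- (nTot - nN + 1L):nTot
        vals <- unlist(lapply(seq_len(nEchoes(series)), function(e) {
            m <- series@magnitude[[e]][, , , idx, drop = FALSE]
            p <- series@phase[[e]][, , , idx, drop = FALSE]
            c(m * cos(p), m * sin(p))
        }))
        if (stats::sd(vals) < .Machine$double.eps^0.5)
            stop("degenerate noise frames: zero variance")
        new("NoiseEstimate", sigma = stats::sd(vals),
            source = "noise_frames", theoreticalFactor = NA_real_)
    } else {
        # most signal-free region: voxels in the lowest 2% of temporal mean
        # magnitude of the last (weakest) echo
        m <- series@magnitude[[nEchoes(series)]]
        nUse <- dim(m)[4] - nNoiseFrames(series)
        m <- m[, , , seq_len(nUse), drop = FALSE]
        mu <- apply(m, 1:3, mean)
        thr <- stats::quantile(mu, 0.02)
        sel <- which(mu <= thr)
        mm <- matrix(m, ncol = nUse)[sel, , drop = FALSE]
        spread <- stats::mad(as.vector(mm - rowMeans(mm)))
        if (spread < .Machine$double.eps^0.5)
            stop("degenerate background: zero variance")
        fac <- 1 / sqrt(2)
        new("NoiseEstimate", sigma = fac * spread,
            source = "theoretical", theoreticalFactor = fac)
    }
}

#' Noise-level singular value edge
#'
#' Monte-Carlo estimate of the largest singular value of an m x n matrix of
#' pure complex Gaussian noise with per-channel (real/imaginary) SD
#' \code{sigma}; components of a data patch at or below this level are
#' indistinguishable from thermal noise. The estimate is the mean largest
#' singular value over \code{mcDraws} seeded draws. Since each complex
#' entry has total SD sigma*sqrt(2), the estimate tracks the asymptotic
#' Marchenko-Pastur edge sigma*sqrt(2)*(sqrt(m) + sqrt(n)).
#'
#' @param m,n integer(1), patch voxel count and frame count (>= 2).
#' @param sigma numeric(1), per-channel noise SD (>= 0).
#' @param mcDraws integer(1), number of Monte-Carlo draws (>= 1).
#' @param seed integer(1).
#' @return numeric(1), the threshold tau.
#' @examples
#' noiseSingularValueEdge(100, 100, sigma = 1, seed = 1)
#' sqrt(2) * (sqrt(100) + sqrt(100))  # asymptotic edge
#' @export
noiseSingularValueEdge <- function(m, n, sigma, mcDraws = 10L, seed = 1L) {
    stopifnot(m >= 2L, n >= 2L, sigma >= 0)
    if (mcDraws < 1L)
        stop("mcDraws must be >= 1")
    if (sigma == 0) return(0)
    withSeed(seed, {
        mean(vapply(seq_len(mcDraws), function(i) {
            X <- matrix(complex(real = stats::rnorm(m * n, 0, sigma),
                                imaginary = stats::rnorm(m * n, 0, sigma)),
                        m, n)
            # largest singular value via the smaller Gram matrix
            if (m >= n) H <- crossprod(Conj(X), X) else H <- X %*% Conj(t(X))
            sqrt(max(Re(eigen(H, symmetric = TRUE,
                              only.values = TRUE)$values)))
        }, numeric(1)))
    })
}

#' Hard-threshold denoising of one Casorati patch
#'
#' Singular value decomposition of the patch-voxels x frames matrix;
#' singular values at or below the threshold \code{tau} are zeroed and the
#' matrix is reconstructed from the surviving components, which are kept
#' unchanged (hard thresholding).
#'
#' @param casorati numeric or complex matrix (patch voxels x frames).
#' @param tau numeric(1), threshold; \code{tau = 0} returns the input.
#' @return the reconstructed matrix, with attribute \code{nRetained}: the
#'   number of components kept.
#' @export
denoisePatch <- function(casorati, tau) {
    stopifnot(is.matrix(casorati), all(is.finite(Mod(casorati))), tau >= 0)
    if (tau == 0) {
        attr(casorati, "nRetained") <- min(dim(casorati))
        return(casorati)
    }
    sv <- svd(casorati)
    keep <- which(sv$d > tau)
    out <- if (length(keep) == 0L) {
        matrix(if (is.complex(casorati)) 0 + 0i else 0,
               nrow(casorati), ncol(casorati))
    } else {
        sv$u[, keep, drop = FALSE] %*%
            (sv$d[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
    }
    attr(out, "nRetained") <- length(keep)
    out
}

# Patch start positions along one axis: stride-spaced, with a final patch
# flush against the boundary so every voxel is covered.
patchStarts <- function(n, p, stride) {
    if (p >= n) return(1L)
    s <- seq.int(1L, n - p + 1L, by = stride)
    if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
    s
}

# Default cubic patch edge: smallest cube with volume >= ratio * nFrames,
# capped at the grid.
defaultPatchEdge <- function(gridShape, nFrames, ratio = 11) {
    edge <- ceiling((ratio * nFrames)^(1 / 3))
    max(2L, min(as.integer(edge), min(gridShape)))
}

#' Patch-based low-rank thermal denoising of a multi-echo run
#'
#' NORDIC-style removal of zero-mean thermal noise. Each echo is denoised
#' independently: the magnitude and phase series form a complex-valued 4D
#' volume; overlapping cubic patches (Casorati matrices: patch voxels x
#' frames) are SVD hard-thresholded at the pure-noise singular value level
#' ([noiseSingularValueEdge()]) and averaged back with uniform weights by
#' coverage count. Trailing noise frames are excluded from the patch time
#' dimension and passed through unchanged. Output magnitude and phase are
#' the modulus and argument of the denoised complex data.
#'
#' Without phase data the same procedure runs on the magnitude alone
#' (magnitude-only mode, with a warning): the residual noise is then
#' non-Gaussian (Rician), which the QC attribute records.
#'
#' @param series a [MultiEchoSeries-class].
#' @param noise a [NoiseEstimate-class], or NULL to estimate from the
#'   series' noise frames.
#' @param patchEdge integer(1), cubic patch edge in voxels; default the
#'   smallest cube with volume >= \code{targetRatio * nFrames}.
#' @param stride integer(1), patch stride in voxels; default half the
#'   patch edge.
#' @param targetRatio numeric(1), spatial:temporal size ratio used for the
#'   default patch (11:1).
#' @param mcDraws integer(1), Monte-Carlo draws for the threshold.
#' @param seed integer(1), seed for the threshold draws.
#' @param gfactor optional 3D array of relative noise amplification used to
#'   pre-normalize spatially varying noise; the output is un-normalized
#'   again. Estimation of g-factor maps is out of scope.
#' @return a denoised [MultiEchoSeries-class] with attribute \code{qc}:
#'   list with \code{sigma}, \code{tau}, \code{patchEdge}, \code{stride},
#'   \code{meanComponentsRetained} (per echo) and \code{magnitudeOnly}.
#' @examples
#' acq <- acquisitionParams(c(15, 40), tr = 2, nFrames = 30, nNoiseFrames = 3,
#'                          gridShape = c(12, 12, 12))
#' run <- simulateRun(acq, tissuePreset("adult"), seed = 1)
#' den <- nordicDenoiseRun(run$series, patchEdge = 6, seed = 2)
#' attr(den, "qc")$tau
#' @export
nordicDenoiseRun <- function(series, noise = NULL, patchEdge = NULL,
                             stride = NULL, targetRatio = 11,
                             mcDraws = 10L, seed = 1L, gfactor = NULL) {
    stopifnot(is(series, "MultiEchoSeries"))
    magnitudeOnly <- !hasPhase(series)
    if (magnitudeOnly)
        warning("no phase data: magnitude-only denoising; residual noise ",
                "is non-Gaussian (recorded in QC)")
    if (is.null(noise))
        noise <- estimateNoiseSigma(
            series, if (magnitudeOnly) "theoretical" else "noise_frames")
    stopifnot(is(noise, "NoiseEstimate"))
    grid <- gridShape(series)
    nT <- nFrames(series)
    nN <- nNoiseFrames(series)
    nTot <- nT + nN
    if (is.null(patchEdge))
        patchEdge <- defaultPatchEdge(grid, nT, targetRatio)
    patchEdge <- as.integer(patchEdge)
    stopifnot(patchEdge >= 2L || prod(pmin(grid, patchEdge)) >= 2L)
    if (is.null(stride)) stride <- max(1L, patchEdge %/% 2L)
    stride <- as.integer(stride)
    stopifnot(stride >= 1L, stride <= patchEdge)
    pdim <- pmin(grid, patchEdge)
    m <- prod(pdim)
    tau <- noiseSingularValueEdge(m, nT, noiseSigma(noise),
                                  mcDraws = mcDraws, seed = seed)

    sx <- patchStarts(grid[1], pdim[1], stride)
    sy <- patchStarts(grid[2], pdim[2], stride)
    sz <- patchStarts(grid[3], pdim[3], stride)

    outMag <- vector("list", nEchoes(series))
    outPhase <- if (magnitudeOnly) list() else vector("list", nEchoes(series))
    compRetained <- numeric(nEchoes(series))
    for (e in seq_len(nEchoes(series))) {
        magE <- series@magnitude[[e]]
        if (magnitudeOnly) {
            cx <- magE[, , , seq_len(nT), drop = FALSE]
        } else {
            phE <- series@phase[[e]]
            cx <- magE[, , , seq_len(nT), drop = FALSE] *
                exp(1i * phE[, , , seq_len(nT), drop = FALSE])
        }
        if (!is.null(gfactor)) {
            stopifnot(identical(dim(gfactor), as.integer(grid)))
            cx <- cx / as.vector(gfactor)
        }
        acc <- array(if (magnitudeOnly) 0 else 0 + 0i, dim(cx))
        cov <- array(0, grid)
        nPatches <- 0L; retained <- 0
        for (ix in sx) for (iy in sy) for (iz in sz) {
            rx <- ix:(ix + pdim[1] - 1L)
            ry <- iy:(iy + pdim[2] - 1L)
            rz <- iz:(iz + pdim[3] - 1L)
            X <- matrix(cx[rx, ry, rz, ], m, nT)
            D <- denoisePatch(X, tau)
            retained <- retained + attr(D, "nRetained")
            nPatches <- nPatches + 1L
            acc[rx, ry, rz, ] <- acc[rx, ry, rz, ] + array(D, c(pdim, nT))
            cov[rx, ry, rz] <- cov[rx, ry, rz] + 1
        }
        acc <- acc / as.vector(cov)
        if (!is.null(gfactor)) acc <- acc * as.vector(gfactor)
        compRetained[e] <- retained / nPatches
        newMag <- magE
        newMag[, , , seq_len(nT)] <- Mod(acc)
        outMag[[e]] <- newMag
        if (!magnitudeOnly) {
            newPh <- series@phase[[e]]
            newPh[, , , seq_len(nT)] <- Arg(acc)
            outPhase[[e]] <- newPh
        }
    }
    out <- multiEchoSeries(outMag, echoTimes = echoTimes(series),
                           tr = repetitionTime(series), phase = outPhase,
                           nNoiseFrames = nN)
    attr(out, "qc") <- list(
        sigma = noiseSigma(noise), sigmaSource = noiseSource(noise),
        tau = tau, patchEdge = patchEdge, stride = stride,
        meanComponentsRetained = compRetained,
        magnitudeOnly = magnitudeOnly)
    out
}
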