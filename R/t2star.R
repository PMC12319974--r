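#' Voxelwise monoexponential T2* and S0 fit
#'
#' Fits \eqn{\bar S(TE) = S_0 \exp(-TE / T2^*)} per voxel by ordinary least
#' squares on the log of the per-echo temporal mean signal (noise frames
#' excluded). When the thermal noise level is supplied, the per-echo mean
#' is noise-floor corrected before the log-fit using the second moment of
#' the magnitude signal: under complex Gaussian noise
#' \eqn{E[M^2] = S^2 + 2\sigma^2}, so
#' \eqn{\hat S = \sqrt{\max(\overline{M^2} - 2\sigma^2, 0)}}. This removes
#' the Rician bias that otherwise flattens the decay at low-signal late
#' echoes.
#'
#' Voxels with a non-positive (or, after correction, zero) mean drop
#' trailing echoes until all used means are positive; \code{nEchoesUsed}
#' records the count. Voxels with fewer than 2 usable echoes are flagged
#' invalid rather than raising an error. T2* is clipped to \code{bounds};
#' voxels with zero or inverted decay hit the upper bound and are still
#' reported valid but can be recognized there. R2* is derived as
#' 1000/T2* (1/s for T2* in ms).
#'
#' @param series a [MultiEchoSeries-class] with >= 2 echoes.
#' @param mask optional logical 3D array; default all voxels.
#' @param bounds numeric(2), T2* clipping bounds in ms. The default
#'   \code{c(2, 500)} covers the infant 95th percentile with headroom
#'   while suppressing log-fit blowups.
#' @param sigma optional numeric(1) or [NoiseEstimate-class]: per-channel
#'   thermal noise SD enabling the noise-floor correction.
#' @return a [T2StarMap-class].
#' @examples
#' acq <- acquisitionParams(c(15, 40, 65), tr = 2, nFrames = 10,
#'                          gridShape = c(10, 10, 10))
#' run <- simulateRun(acq, tissuePreset("adult"),
#'                    noise = noiseModel(thermalSigma = 0), seed = 1)
#' t2map <- fitT2Star(run$series, mask = run$truth$mask)
#' t2map
#' @export
fitT2Star <- function(series, mask = NULL, bounds = c(2, 500), sigma = NULL) {
    stopifnot(is(series, "MultiEchoSeries"))
    te <- echoTimes(series)
    if (length(te) < 2L)
        stop("T2* fitting needs at least 2 echoes")
    stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[2] > bounds[1])
    if (is(sigma, "NoiseEstimate")) sigma <- noiseSigma(sigma)
    grid <- gridShape(series)
    if (is.null(mask)) mask <- array(TRUE, grid)
    stopifnot(identical(dim(mask), as.integer(grid)))
    nT <- nFrames(series)
    vIdx <- which(mask)
    nV <- length(vIdx)
    E <- length(te)

    # per-voxel, per-echo mean signal (noise-floor corrected if sigma known)
    S <- matrix(NA_real_, nV, E)
    for (e in seq_len(E)) {
        m <- matrix(series@magnitude[[e]], ncol = dim(series@magnitude[[e]])[4])
        m <- m[vIdx, seq_len(nT), drop = FALSE]
        if (is.null(sigma)) {
            S[, e] <- rowMeans(m)
        } else {
            S[, e] <- sqrt(pmax(rowMeans(m^2) - 2 * sigma^2, 0))
        }
    }

    # drop trailing echoes until all used means are positive
    nUse <- rep(E, nV)
    bad <- S <= 0
    if (any(bad)) {
        lastBad <- apply(bad, 1L, function(b) {
            w <- which(b)
            if (length(w) == 0L) 0L else E - min(w) + 1L
        })
        # a non-positive echo invalidates itself and everything after it
        nUse <- E - lastBad
    }

    t2 <- s0 <- rmse <- rep(NA_real_, nV)
    valid <- nUse >= 2L
    logS <- suppressWarnings(log(S))
    for (k in sort(unique(nUse[valid]))) {
        sel <- which(nUse == k)
        tek <- te[seq_len(k)]
        X <- cbind(1, tek)
        # closed-form OLS for all voxels with this echo count at once
        XtXi <- solve(crossprod(X))
        B <- logS[sel, seq_len(k), drop = FALSE] %*% X %*% XtXi   # nSel x 2
        slope <- B[, 2L]
        fit <- B %*% t(X)
        res <- logS[sel, seq_len(k), drop = FALSE] - fit
        rmse[sel] <- sqrt(rowMeans(res^2))
        t2k <- ifelse(slope < 0, -1 / slope, bounds[2])
        t2[sel] <- pmin(pmax(t2k, bounds[1]), bounds[2])
        s0[sel] <- exp(B[, 1L])
    }

    asGrid <- function(v, fill = NA_real_) {
        a <- array(fill, grid); a[vIdx] <- v; a
    }
    validArr <- array(FALSE, grid)
    validArr[vIdx] <- valid
    new("T2StarMap",
        t2star = asGrid(ifelse(valid, t2, NA_real_)),
        s0 = asGrid(ifelse(valid, s0, NA_real_)),
        r2star = asGrid(ifelse(valid, 1000 / t2, NA_real_)),
        fitRMSE = asGrid(ifelse(valid, rmse, NA_real_)),
        nEchoesUsed = asGrid(nUse, fill = 0L),
        valid = validArr, bounds = as.numeric(bounds))
}

#' T2*-weighted optimal combination weights
#'
#' Normalized echo weights \eqn{w_e \propto TE_e \exp(-TE_e / T2^*)},
#' the weighting that maximizes BOLD contrast-to-noise for tissue with the
#' given T2*. Longer T2* (e.g. neonatal tissue) shifts weight toward later
#' echoes.
#'
#' @param echoTimes numeric, echo times in ms (positive).
#' @param t2star numeric, one or more T2* values in ms (positive).
#' @return if \code{t2star} is scalar, a numeric vector of weights summing
#'   to 1; otherwise a matrix (length(t2star) x echoes).
#' @examples
#' te <- c(14.2, 38.93, 63.66, 88.39, 113.12)
#' round(weightsAtT2Star(te, 50.71), 3)  # adult median cortical T2*
#' round(weightsAtT2Star(te, 98.58), 3)  # newborn median cortical T2*
#' @export
weightsAtT2Star <- function(echoTimes, t2star) {
    stopifnot(all(echoTimes > 0))
    if (any(!is.finite(t2star) | t2star <= 0))
        stop("t2star must be positive")
    W <- outer(t2star, echoTimes,
               function(t2, te) te * exp(-te / t2))
    W <- W / rowSums(W)
    if (length(t2star) == 1L) drop(W) else W
}

#' Optimally combine a multi-echo series
#'
#' Weighted sum of the echo series with voxelwise weights from the T2* map
#' ([weightsAtT2Star()]). Voxels with an invalid fit fall back to equal
#' weights and are flagged in the returned attribute. All frames,
#' including trailing noise frames, are combined with the same weights.
#'
#' @param series a [MultiEchoSeries-class].
#' @param t2smap a [T2StarMap-class] on the same grid.
#' @return a single-echo [MultiEchoSeries-class]; its echo time is the
#'   weight-averaged TE over valid voxels (an effective TE, metadata
#'   only). Attribute \code{equalWeightVoxels} counts fallback voxels.
#' @examples
#' acq <- acquisitionParams(c(15, 40, 65), tr = 2, nFrames = 10,
#'                          gridShape = c(10, 10, 10))
#' run <- simulateRun(acq, tissuePreset("adult"),
#'                    noise = noiseModel(thermalSigma = 0), seed = 1)
#' t2map <- fitT2Star(run$series)
#' comb <- optimalCombine(run$series, t2map)
#' @export
optimalCombine <- function(series, t2smap) {
    stopifnot(is(series, "MultiEchoSeries"), is(t2smap, "T2StarMap"))
    grid <- gridShape(series)
    stopifnot(identical(dim(t2smap@t2star), as.integer(grid)))
    te <- echoTimes(series)
    E <- length(te)
    nVox <- prod(grid)
    valid <- as.vector(t2smap@valid)
    W <- matrix(1 / E, nVox, E)
    if (any(valid))
        W[valid, ] <- weightsAtT2Star(te, t2smap@t2star[valid])
    if (E == 1L) W[] <- 1
    nTot <- dim(series@magnitude[[1L]])[4]
    comb <- matrix(0, nVox, nTot)
    for (e in seq_len(E))
        comb <- comb + W[, e] * matrix(series@magnitude[[e]], nVox, nTot)
    effTE <- if (any(valid)) sum(colMeans(W[valid, , drop = FALSE]) * te)
             else mean(te)
    out <- multiEchoSeries(array(comb, c(grid, nTot)), echoTimes = effTE,
                           tr = repetitionTime(series),
                           nNoiseFrames = nNoiseFrames(series))
    attr(out, "equalWeightVoxels") <- sum(!valid)
    out
}

#' Summary table of optimal-combination weights
#'
#' Distribution of the normalized echo weights over a mask: mean, median,
#' SD, 5th and 95th percentile per echo, together with the same summaries
#' of T2* (the familiar per-subject weight-table layout).
#'
#' @param t2smap a [T2StarMap-class].
#' @param echoTimes numeric, echo times in ms.
#' @param mask optional logical 3D array; default the map's valid voxels.
#' @return a data.frame with rows mean/median/sd/p05/p95; first column
#'   \code{t2star}, then one column per echo.
#' @examples
#' te <- c(14.2, 38.93, 63.66, 88.39, 113.12)
#' acq <- acquisitionParams(te, tr = 1.761, nFrames = 10,
#'                          gridShape = c(12, 12, 12))
#' run <- simulateRun(acq, tissuePreset("infant"),
#'                    noise = noiseModel(thermalSigma = 0), seed = 1)
#' ws <- weightSummary(fitT2Star(run$series), te)
#' round(ws, 3)
#' @export
weightSummary <- function(t2smap, echoTimes, mask = NULL) {
    stopifnot(is(t2smap, "T2StarMap"))
    if (is.null(mask)) mask <- t2smap@valid
    sel <- mask & t2smap@valid
    if (!any(sel))
        stop("empty mask: no valid voxels to summarize")
    t2 <- t2smap@t2star[sel]
    W <- weightsAtT2Star(echoTimes, t2)
    if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
    summarize <- function(x) c(mean = mean(x), median = stats::median(x),
                               sd = stats::sd(x),
                               p05 = unname(stats::quantile(x, 0.05)),
                               p95 = unname(stats::quantile(x, 0.95)))
    tab <- cbind(t2star = summarize(t2),
                 apply(W, 2L, summarize))
    colnames(tab) <- c("t2star", paste0("echo", seq_along(echoTimes)))
    as.data.frame(tab)
}
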