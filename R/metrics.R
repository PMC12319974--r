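# Accept a single-echo series or a bare 4D array; returns list(data, nNoise).
asSingle4d <- function(x) {
    if (is(x, "MultiEchoSeries")) {
        if (nEchoes(x) != 1L)
            stop("expected a single-echo series (combine or extract first)")
        list(data = x@magnitude[[1L]], nNoise = nNoiseFrames(x))
    } else {
        stopifnot(length(dim(x)) == 4L)
        list(data = x, nNoise = 0L)
    }
}

#' Temporal SNR map
#'
#' Voxelwise temporal mean divided by temporal standard deviation.
#' Trailing noise frames are excluded by default and no motion censoring
#' is applied (by convention tSNR is computed on the full run). Voxels
#' with zero temporal SD are flagged undefined, not set to infinity.
#'
#' @param x single-echo [MultiEchoSeries-class] or 4D array.
#' @param excludeNoiseFrames logical(1).
#' @param mask optional logical 3D array restricting the map.
#' @param conditionLabel character(1), free condition tag.
#' @return a [TsnrMap-class].
#' @examples
#' dat <- array(rnorm(4^3 * 100, mean = 100, sd = 5), c(4, 4, 4, 100))
#' m <- tsnrMap(dat)
#' mean(tsnrValues(m))  # ~20
#' @export
tsnrMap <- function(x, excludeNoiseFrames = TRUE, mask = NULL,
                    conditionLabel = "") {
    s <- asSingle4d(x)
    dat <- s$data
    nTot <- dim(dat)[4]
    nUse <- if (excludeNoiseFrames) nTot - s$nNoise else nTot
    if (nUse < 2L) stop("need at least 2 frames")
    dat <- dat[, , , seq_len(nUse), drop = FALSE]
    grid <- dim(dat)[1:3]
    V <- matrix(dat, prod(grid), nUse)
    mu <- rowMeans(V)
    sd <- sqrt(rowSums((V - mu)^2) / (nUse - 1L))
    defined <- sd > 0
    if (!is.null(mask)) {
        stopifnot(identical(dim(mask), as.integer(grid)))
        defined <- defined & as.vector(mask)
    }
    vals <- rep(NA_real_, length(mu))
    vals[defined] <- mu[defined] / sd[defined]
    new("TsnrMap", values = array(vals, grid),
        defined = array(defined, grid),
        runsUsed = integer(), conditionLabel = conditionLabel)
}

#' Average tSNR maps over selected runs
#'
#' Voxelwise mean of per-run tSNR maps over qualifying runs (conventionally
#' those with >90\% low-motion frames, see [selectRuns()]), with a summary
#' over in-mask voxels. The summary SD is taken across brain locations,
#' not across runs.
#'
#' @param maps list of [TsnrMap-class], one per run.
#' @param keep integer, indices of qualifying runs (e.g. from
#'   [selectRuns()]); default all.
#' @param conditionLabel character(1).
#' @return a [TsnrMap-class]; attribute \code{summary} holds \code{mean}
#'   and \code{sd} over voxels defined in every averaged run.
#' @export
averageTsnr <- function(maps, keep = seq_along(maps), conditionLabel = "") {
    stopifnot(length(maps) >= 1L, all(vapply(maps, is, TRUE, "TsnrMap")))
    if (length(keep) == 0L) stop("empty run selection")
    maps <- maps[keep]
    defined <- Reduce("&", lapply(maps, function(m) m@defined))
    acc <- Reduce("+", lapply(maps, function(m)
        ifelse(m@defined, m@values, 0)))
    vals <- array(NA_real_, dim(defined))
    vals[defined] <- acc[defined] / length(maps)
    out <- new("TsnrMap", values = vals, defined = defined,
               runsUsed = as.integer(keep), conditionLabel = conditionLabel)
    v <- vals[defined]
    attr(out, "summary") <- c(mean = mean(v), sd = stats::sd(v))
    out
}

#' Percent difference
#'
#' \code{100 * (after - before) / before}: the relative change of a summary
#' statistic (e.g. mean tSNR or reliability) from a baseline condition.
#' Deliberately asymmetric -- the baseline is the denominator.
#'
#' @param before,after numeric, baseline and comparison values;
#'   \code{before} must be positive.
#' @return numeric, percent change (not rounded).
#' @examples
#' percentDifference(67.93, 85.11)  # 25.29
#' @export
percentDifference <- function(before, after) {
    if (any(before <= 0)) stop("baseline must be positive")
    100 * (after - before) / before
}

#' Estimate spatial smoothness (FWHM)
#'
#' Global smoothness of a 4D series from the lag-1 spatial autocorrelation
#' of detrended residuals. Per axis, neighboring-voxel residuals are
#' correlated over all frames; modeling the data as white noise smoothed
#' with a Gaussian kernel of width \eqn{\sigma_k} (so the ACF is
#' \eqn{r(d) = \exp(-d^2 / (4\sigma_k^2))}), the kernel-equivalent FWHM is
#' \eqn{\sqrt{8 \ln 2}\,\sigma_k}. The reported FWHM combines the
#' kernel-equivalent FWHM with the voxel size in quadrature, so an
#' unsmoothed white-noise volume reports approximately the voxel size
#' (its intrinsic resolution) rather than zero.
#'
#' @param x single-echo [MultiEchoSeries-class] or 4D array.
#' @param mask optional logical 3D array.
#' @param voxelSize numeric(1), mm.
#' @return list with \code{fwhm} (mm, average over axes),
#'   \code{fwhmPerAxis}, and \code{acf} (lag-1 r per axis).
#' @export
estimateFwhm <- function(x, mask = NULL, voxelSize = 2) {
    s <- asSingle4d(x)
    dat <- s$data
    nUse <- dim(dat)[4] - s$nNoise
    dat <- dat[, , , seq_len(nUse), drop = FALSE]
    grid <- dim(dat)[1:3]
    if (any(grid < 8L)) stop("grid must be >= 8 voxels per axis")
    if (is.null(mask)) mask <- array(TRUE, grid)
    # detrend: remove per-voxel mean and linear trend
    tt <- seq_len(nUse)
    X <- cbind(1, tt - mean(tt))
    V <- matrix(dat, prod(grid), nUse)
    B <- V %*% X %*% solve(crossprod(X))
    R <- V - B %*% t(X)
    R4 <- array(R, c(grid, nUse))
    acf1 <- numeric(3)
    sub <- function(arr, ax, idx) {
        switch(ax,
               arr[idx, , , , drop = FALSE],
               arr[, idx, , , drop = FALSE],
               arr[, , idx, , drop = FALSE])
    }
    sub3 <- function(arr, ax, idx) {
        switch(ax,
               arr[idx, , , drop = FALSE],
               arr[, idx, , drop = FALSE],
               arr[, , idx, drop = FALSE])
    }
    for (ax in 1:3) {
        n <- grid[ax]
        a <- sub(R4, ax, 1:(n - 1L))
        b <- sub(R4, ax, 2:n)
        mPair <- sub3(mask, ax, 1:(n - 1L)) & sub3(mask, ax, 2:n)
        aM <- matrix(a, prod(dim(a)[1:3]), nUse)[as.vector(mPair), ]
        bM <- matrix(b, prod(dim(b)[1:3]), nUse)[as.vector(mPair), ]
        acf1[ax] <- stats::cor(as.vector(aM), as.vector(bM))
    }
    fwhmK <- vapply(acf1, function(r) {
        if (!is.finite(r) || r <= 0) return(0)
        sigmaK <- sqrt(-1 / (4 * log(r)))         # voxels
        sqrt(8 * log(2)) * sigmaK * voxelSize     # mm
    }, numeric(1))
    fwhmPerAxis <- sqrt(fwhmK^2 + voxelSize^2)
    list(fwhm = mean(fwhmPerAxis), fwhmPerAxis = fwhmPerAxis, acf = acf1)
}

#' Smooth a series to a target FWHM
#'
#' Applies the separable Gaussian kernel whose width, added in quadrature
#' to the current estimated smoothness, yields the target FWHM
#' (\eqn{FWHM_{add}^2 = FWHM_{target}^2 - FWHM_{current}^2}). Used to
#' equate smoothness across conditions before comparing tSNR.
#'
#' @param x single-echo [MultiEchoSeries-class] or 4D array.
#' @param targetFwhm numeric(1), mm; must be >= the current estimate.
#' @param mask optional logical 3D array for the estimation step.
#' @param voxelSize numeric(1), mm.
#' @return object of the same kind as the input, smoothed; attribute
#'   \code{appliedFwhm} records the kernel used.
#' @export
smoothToFwhm <- function(x, targetFwhm, mask = NULL, voxelSize = 2) {
    cur <- estimateFwhm(x, mask = mask, voxelSize = voxelSize)$fwhm
    if (targetFwhm < cur - 1e-8)
        stop(sprintf("target FWHM %.3g mm below current estimate %.3g mm",
                     targetFwhm, cur))
    addF <- sqrt(max(targetFwhm^2 - cur^2, 0))
    sigmaVox <- addF / (sqrt(8 * log(2)) * voxelSize)
    s <- asSingle4d(x)
    sm <- if (sigmaVox > 0) gaussianSmooth4d(s$data, sigmaVox) else s$data
    out <- if (is(x, "MultiEchoSeries")) {
        multiEchoSeries(sm, echoTimes = echoTimes(x),
                        tr = repetitionTime(x),
                        nNoiseFrames = nNoiseFrames(x))
    } else sm
    attr(out, "appliedFwhm") <- addF
    out
}
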